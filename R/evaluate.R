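# Rank-based evaluation of pair scores against truth labels: precision-recall
# curve, PRAUC, and positives detected at a recall (TPR) threshold. Designed
# for the heavily imbalanced setting of co-evolution screening, where PR
# curves are more informative than ROC.

#' Precision-recall curve with tie grouping
#'
#' Pairs are ranked by descending score; all pairs sharing one score enter
#' the curve as a single block, so the curve does not depend on input order.
#'
#' @param score Numeric scores, higher = more confident positive (use e.g.
#'   `-log10(p_value)`).
#' @param label Logical (or 0/1) truth labels, same length.
#' @return Data frame with one row per distinct score: `threshold`, `tp`,
#'   `fp`, `recall`, `precision`.
#' @export
pr_curve <- function(score, label) {
  label <- as.logical(label)
  stopifnot(length(score) == length(label), !anyNA(score), !anyNA(label))
  P <- sum(label)
  if (P == 0L) stop("no positive labels")
  if (!any(!label)) stop("no negative labels")
  ord <- order(score, decreasing = TRUE)
  score <- score[ord]
  label <- label[ord]
  last <- cumsum(rle(score)$lengths)  # last index of each tie block
  tp <- cumsum(label)[last]
  fp <- cumsum(!label)[last]
  data.frame(threshold = score[last], tp = tp, fp = fp,
             recall = tp / P, precision = tp / (tp + fp))
}

#' Area under the precision-recall curve
#'
#' Step-wise (interpolation-free) area: the sum over tie blocks of the
#' recall increment times the precision at that block. A random or constant
#' scoring yields the prevalence of positives; perfect separation yields 1.
#'
#' @inheritParams pr_curve
#' @return PRAUC in \[0, 1\].
#' @export
prauc <- function(score, label) {
  pc <- pr_curve(score, label)
  sum(diff(c(0, pc$recall)) * pc$precision)
}

#' True positives detected at a recall threshold
#'
#' Number of true positives above the smallest score cutoff whose recall
#' reaches at least `tpr`. Non-decreasing in `tpr`: a laxer recall target
#' admits a laxer threshold and therefore fewer detected positives.
#'
#' @inheritParams pr_curve
#' @param tpr Target recall in (0, 1].
#' @return Integer count of true positives at the threshold.
#' @export
positives_at_tpr <- function(score, label, tpr) {
  stopifnot(tpr > 0, tpr <= 1)
  pc <- pr_curve(score, label)
  i <- which(pc$recall >= tpr)[1L]
  if (is.na(i)) return(sum(as.logical(label)))  # recall 1 is always reached
  pc$tp[i]
}

#' Rank method results against truth labels
#'
#' Joins a [run_method] result table to a truth table and produces the
#' score/label vectors used by [prauc] and [positives_at_tpr]. Pairs absent
#' from the truth table are dropped (unlabeled pairs are not evaluated); the
#' score is `-log10(p_value)`. By default both association directions are
#' ranked together; `direction = "coevolved"` keeps positively associated
#' pairs only (others get score 0).
#'
#' @param results Data frame from [run_method].
#' @param truth Data frame with columns `og1`, `og2` and a logical label
#'   column (default `coevolved`).
#' @param label_col Name of the label column in `truth`.
#' @param direction `"both"` (default) or `"coevolved"`.
#' @return Data frame with `og1`, `og2`, `score`, `label`.
#' @export
ranked_pairs <- function(results, truth, label_col = "coevolved",
                         direction = c("both", "coevolved")) {
  direction <- match.arg(direction)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  idx <- match(key(results$og1, results$og2), key(truth$og1, truth$og2))
  keep <- !is.na(idx)
  res <- results[keep, , drop = FALSE]
  score <- -log10(pmax(res$p_value, .Machine$double.xmin))
  if (direction == "coevolved") {
    assoc <- if ("k" %in% names(res)) {
      res$k > 0
    } else {
      res$c11 * res$c00 > res$c10 * res$c01
    }
    score[!assoc] <- 0
  }
  data.frame(og1 = res$og1, og2 = res$og2, score = score,
             label = as.logical(truth[[label_col]][idx[keep]]),
             stringsAsFactors = FALSE)
}
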