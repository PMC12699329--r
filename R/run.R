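# Dispatcher: score OG pairs with any of the six methods and return a tidy
# per-pair result table.

weighted_method_names <- c("naive", "rle", "cwa", "asa", "asa_unweighted")
transition_method_names <- c("cotransitions", "sev")

#' Score OG pairs for co-evolution
#'
#' Runs one of the six profiling methods over all unordered OG pairs of a
#' profile (or a supplied pair list) and reports, per pair, the contingency
#' table or event counts, the exact-test p-value, and the direction of the
#' association.
#'
#' @param phy A prepared binary rooted `phylo` (see [prepare_tree]).
#' @param profile Profile matrix (genomes x OGs, 0/1); rows must match the
#'   tree leaves.
#' @param method One of `"naive"`, `"rle"`, `"cwa"`, `"asa"`,
#'   `"asa_unweighted"`, `"cotransitions"`, `"sev"`.
#' @param pairs Optional two-column data frame (`og1`, `og2`) restricting
#'   which pairs are scored; default all `m(m-1)/2` unordered pairs.
#' @param anc Optional external ancestral-state matrix (nodes x OGs) for ASA
#'   or SEV; by default ASA and SEV reconstruct states internally with
#'   Fitch/ACCTRAN parsimony.
#' @param alternative Sidedness of Fisher's test for the weighted methods
#'   (`"two.sided"` default, `"greater"` optional); transition methods are
#'   one-tailed by construction.
#' @param alpha Significance level used only to call the `direction` column.
#' @param bh Add a Benjamini-Hochberg adjusted p-value column and use it for
#'   the direction call.
#' @param root_tie,asa_stem,collapse_consecutive Method options passed to
#'   [acctran], [asa_correct] and [cotransition_events].
#' @return Data frame with columns `og1`, `og2`, `method`; `c11`, `c10`,
#'   `c01`, `c00` (weighted methods) or `k`, `t1`, `t2`, `n` (transition
#'   methods); `p_value`, optionally `p_adjusted`, and `direction`
#'   (`"coevolved"`, `"contrapositive"` or `"none"`).
#' @export
run_method <- function(phy, profile, method, pairs = NULL, anc = NULL,
                       alternative = c("two.sided", "greater"),
                       alpha = 0.05, bh = FALSE, root_tie = "absent",
                       asa_stem = "include", collapse_consecutive = FALSE) {
  method <- match.arg(method, c(weighted_method_names,
                                transition_method_names))
  alternative <- match.arg(alternative)
  profile <- validate_profile(profile, tree = phy)
  ogs <- colnames(profile)
  if (is.null(pairs)) {
    if (length(ogs) < 2L) stop("need at least two OGs")
    cmb <- utils::combn(ogs, 2L)
    pairs <- data.frame(og1 = cmb[1L, ], og2 = cmb[2L, ],
                        stringsAsFactors = FALSE)
  } else {
    pairs <- data.frame(og1 = as.character(pairs[[1L]]),
                        og2 = as.character(pairs[[2L]]),
                        stringsAsFactors = FALSE)
    bad <- setdiff(unique(c(pairs$og1, pairs$og2)), ogs)
    if (length(bad)) stop("pair list names unknown OGs: ",
                          paste(bad, collapse = ", "))
  }
  res <- if (method %in% transition_method_names) {
    run_transition(phy, profile, method, pairs, anc, root_tie,
                   collapse_consecutive)
  } else {
    run_weighted(phy, profile, method, pairs, anc, alternative, root_tie,
                 asa_stem)
  }
  res$method <- method
  p_call <- res$p_value
  if (bh) {
    res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
    p_call <- res$p_adjusted
  }
  sig <- p_call <= alpha
  assoc <- if (method %in% transition_method_names) {
    sign(res$k)
  } else {
    sign(res$c11 * res$c00 - res$c10 * res$c01)
  }
  res$direction <- ifelse(sig & assoc > 0, "coevolved",
                          ifelse(sig & assoc < 0, "contrapositive", "none"))
  first <- c("og1", "og2", "method")
  res[, c(first, setdiff(names(res), first))]
}

run_weighted <- function(phy, profile, method, pairs, anc, alternative,
                         root_tie, asa_stem) {
  use_asa <- method %in% c("asa", "asa_unweighted")
  if (use_asa) {
    used <- unique(c(pairs$og1, pairs$og2))
    if (is.null(anc)) {
      anc <- reconstruct_ancestral(phy, profile[, used, drop = FALSE],
                                   root_tie = root_tie)
    } else {
      idx <- tree_index(phy)
      anc <- anc[idx$labels, , drop = FALSE]
      # leaf rows must mirror the observed profile
      anc[seq_len(idx$ntip), used] <- profile[phy$tip.label, used]
    }
  }
  cells <- matrix(0, nrow = nrow(pairs), ncol = 4L,
                  dimnames = list(NULL, cell_names))
  for (i in seq_len(nrow(pairs))) {
    o1 <- pairs$og1[i]; o2 <- pairs$og2[i]
    cells[i, ] <- switch(
      method,
      naive = naive_counts(profile[, o1], profile[, o2]),
      rle = rle_counts(phy, profile[, o1], profile[, o2]),
      cwa = cwa_counts(phy, profile[, o1], profile[, o2]),
      asa = asa_counts(phy, anc[, o1], anc[, o2], weighted = TRUE,
                       stem = asa_stem),
      asa_unweighted = asa_counts(phy, anc[, o1], anc[, o2],
                                  weighted = FALSE, stem = asa_stem))
  }
  p <- fisher_exact(cells[, "c11"], cells[, "c10"], cells[, "c01"],
                    cells[, "c00"], alternative = alternative)
  data.frame(pairs, cells, p_value = p, stringsAsFactors = FALSE)
}

run_transition <- function(phy, profile, method, pairs, anc, root_tie,
                           collapse_consecutive) {
  E <- if (method == "sev") {
    sev_events(phy, profile, anc = anc, root_tie = root_tie)
  } else {
    cotransition_events(phy, profile,
                        collapse_consecutive = collapse_consecutive)
  }
  n <- attr(E, "n")
  K <- all_pairs_k(E)
  i1 <- match(pairs$og1, colnames(profile))
  i2 <- match(pairs$og2, colnames(profile))
  k <- K[cbind(i1, i2)]
  t1 <- diag(K)[i1]
  t2 <- diag(K)[i2]
  tst <- sev_test(k, t1, t2, n)
  data.frame(pairs, k = k, t1 = t1, t2 = t2, n = n,
             p_value = tst$p_value, out_of_support = tst$out_of_support,
             stringsAsFactors = FALSE)
}
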