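# Exact hypergeometric machinery shared by all scoring methods.

#' Fisher's exact test on a 2x2 table
#'
#' Vectorized exact test with the two alternatives used by the scoring
#' methods. `greater` is the exact upper hypergeometric tail
#' `P(X >= a)` with all margins fixed; `two.sided` sums the probabilities of
#' all tables whose point probability does not exceed that of the observed
#' table (with a relative tolerance of 1e-7 to absorb floating-point noise,
#' the usual convention). All four cell arguments recycle.
#'
#' @param a,b,c,d Nonnegative integer cells: `a` = both present, `b` = first
#'   only, `c` = second only, `d` = neither (or the analogous layout for
#'   event tables).
#' @param alternative `"two.sided"` or `"greater"`.
#' @return Numeric vector of p-values in (0, 1].
#' @examples
#' fisher_exact(2, 0, 0, 8, alternative = "greater")  # 1/45
#' @export
fisher_exact <- function(a, b, c, d, alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  if (any(a < 0 | b < 0 | c < 0 | d < 0) || anyNA(a + b + c + d))
    stop("cells must be nonnegative and non-missing")
  m1 <- a + b   # row-1 margin (white balls)
  m2 <- c + d   # row-2 margin (black balls)
  k1 <- a + c   # column-1 margin (draws)
  if (alternative == "greater")
    return(pmin(1, stats::phyper(a - 1, m1, m2, k1, lower.tail = FALSE)))
  p <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(0, k1[i] - m2[i])
    hi <- min(m1[i], k1[i])
    x <- lo:hi
    pr <- stats::dhyper(x, m1[i], m2[i], k1[i])
    p[i] <- sum(pr[pr <= pr[x == a[i]] * (1 + 1e-7)])
  }
  pmin(1, p)
}
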