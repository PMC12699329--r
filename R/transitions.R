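# Transition (event-counting) methods: cotransitions (leaf-order based) and
# the simultaneous evolution test, SEV (branch based, on reconstructed
# ancestral states). Both reduce to an event matrix E in {-1, 0, +1}
# (rows = gaps or branches, columns = OGs); all-versus-all concordance
# k = t(E) %*% E is a single matrix product, which is what makes these
# methods scale to tens of thousands of OGs.

#' Cotransition event matrix
#'
#' Profiles are laid out in the tree's depth-first leaf order; the gap
#' between adjacent genomes g and g+1 carries `+1` when the OG state goes
#' 0 to 1, `-1` for 1 to 0, `0` otherwise. The population size of the exact
#' test is `n = genomes - 1` (transitions live between genomes). Like RLE,
#' the result depends on the drawn orientation of the tree.
#'
#' @param phy A rooted `phylo`.
#' @param profile Profile matrix (genomes x OGs, 0/1).
#' @param collapse_consecutive If `TRUE`, an event is zeroed when the same OG
#'   already has a (kept) non-zero event in the immediately preceding gap,
#'   approximating the original cotransitions rule that consecutive changes
#'   are ignored. Default `FALSE`: the plain matrix form.
#' @return Integer matrix in `{-1, 0, 1}` with `genomes - 1` rows; attribute
#'   `n` = number of gaps.
#' @export
cotransition_events <- function(phy, profile, collapse_consecutive = FALSE) {
  ord <- leaf_order(phy)
  X <- profile[ord, , drop = FALSE]
  L <- nrow(X)
  E <- X[-1L, , drop = FALSE] - X[-L, , drop = FALSE]
  storage.mode(E) <- "integer"
  if (collapse_consecutive && nrow(E) > 1L) {
    for (j in seq_len(ncol(E))) {
      for (g in 2:nrow(E)) {
        if (E[g, j] != 0L && E[g - 1L, j] != 0L) E[g, j] <- 0L
      }
    }
  }
  rownames(E) <- paste(ord[-L], ord[-1L], sep = "|")
  attr(E, "n") <- L - 1L
  E
}

#' SEV event matrix
#'
#' One row per branch of the tree: the gain/loss of each OG mapped from
#' reconstructed ancestral states by [states_to_events]. States come from
#' internal Fitch/ACCTRAN parsimony by default, which guarantees the SEV
#' constraint that an OG is never gained (or lost) in parallel on both child
#' branches of one node; under that constraint the population size of the
#' exact test is `n` = number of internal nodes, not the number of branches.
#' User-supplied states are checked against the constraint.
#'
#' @param phy A binary rooted `phylo`.
#' @param profile Profile matrix (genomes x OGs); used for internal
#'   parsimony and leaf states.
#' @param anc Optional externally reconstructed state matrix
#'   (nodes x OGs, as from [read_ancestral_table]); overrides parsimony.
#' @param root_tie Passed to [acctran] for the internal reconstruction.
#' @return Integer event matrix (branches x OGs) with attribute `n` =
#'   number of internal nodes.
#' @export
sev_events <- function(phy, profile, anc = NULL, root_tie = "absent") {
  idx <- tree_index(phy)
  if (is.null(anc)) {
    anc <- reconstruct_ancestral(phy, profile, root_tie = root_tie)
  } else {
    anc <- anc[idx$labels, colnames(profile), drop = FALSE]
  }
  E <- states_to_events(phy, anc)
  if (!is.null(anc)) check_no_parallel(phy, E)
  attr(E, "n") <- idx$nnode
  E
}

# error if any OG has same-direction changes on both child branches of a node
check_no_parallel <- function(phy, E) {
  idx <- tree_index(phy)
  internals <- which(lengths(idx$children) == 2L)
  row_of <- match(idx$labels, rownames(E))
  for (v in internals) {
    ch <- idx$children[[v]]
    r1 <- row_of[ch[1L]]
    r2 <- row_of[ch[2L]]
    bad <- which(E[r1, ] != 0L & E[r1, ] == E[r2, ])
    if (length(bad))
      stop(sprintf(
        "parallel %s of OG %s on both child branches of node %s violates the SEV constraint",
        if (E[r1, bad[1L]] > 0) "gain" else "loss",
        colnames(E)[bad[1L]], idx$labels[v]))
  }
  invisible(TRUE)
}

#' All-pairs concordance score by matrix multiplication
#'
#' `K = t(E) %*% E`: for OGs i and j, `K[i, j]` is the number of rows where
#' both have an event in the same direction minus the number where the
#' directions oppose — concordances minus discordances. The diagonal holds
#' each OG's event count `t`.
#'
#' @param E Event matrix in `{-1, 0, 1}` (rows = branches or gaps,
#'   columns = OGs).
#' @return Integer matrix OGs x OGs.
#' @export
all_pairs_k <- function(E) {
  if (!all(E %in% c(-1L, 0L, 1L))) stop("event entries must be -1, 0 or 1")
  K <- crossprod(E)
  storage.mode(K) <- "integer"
  K
}

#' SEV/cotransitions exact test on event counts
#'
#' One-tailed Fisher's exact test on the table
#' `(|k|, t1 - |k|; t2 - |k|, n - t1 - t2 + |k|)`:
#' `p = P(X >= |k|)` for hypergeometric `X` with margins `(t1, n - t1)` and
#' `(t2, n - t2)` in a population of size `n`. The sign of `k` gives the
#' direction: positive = co-evolved, negative = contrapositive. Tables with
#' `n - t1 - t2 + |k| < 0` lie outside hypergeometric support (impossible
#' under the internal parsimony constraint, reachable with user-supplied
#' states); they get the p-value of the most extreme supported table (1) and
#' are flagged.
#'
#' @param k Signed concordance score(s).
#' @param t1,t2 Event counts of the two OGs.
#' @param n Population size: internal nodes (SEV) or genomes - 1
#'   (cotransitions).
#' @return Data frame with columns `p_value` and `out_of_support`.
#' @examples
#' sev_test(2, 2, 2, 10)$p_value  # 1/45
#' @export
sev_test <- function(k, t1, t2, n) {
  len <- max(length(k), length(t1), length(t2), length(n))
  k <- rep_len(k, len); t1 <- rep_len(t1, len)
  t2 <- rep_len(t2, len); n <- rep_len(n, len)
  if (any(t1 < 0 | t2 < 0 | n < 0)) stop("t1, t2 and n must be nonnegative")
  if (any(abs(k) > pmin(t1, t2))) stop("|k| cannot exceed min(t1, t2)")
  ak <- abs(k)
  p <- pmin(1, stats::phyper(ak - 1, t1, n - t1, t2, lower.tail = FALSE))
  data.frame(p_value = p, out_of_support = (n - t1 - t2 + ak) < 0)
}
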