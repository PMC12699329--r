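# Maximum-parsimony ancestral reconstruction for binary presence/absence
# characters: Fitch bottom-up sets, an ACCTRAN-style top-down resolution,
# and the mapping of node states to branch gain/loss events.

# Fitch sets are encoded as 2-bit masks: 1 = {0}, 2 = {1}, 3 = {0,1}.

#' Fitch bottom-up pass for binary characters
#'
#' Computes the Fitch state set at every node and the parsimony score
#' (minimum number of state changes) for each profile column, by
#' intersection-else-union over the two children of every internal node.
#'
#' @param phy A binary rooted `phylo` (see [prepare_tree]).
#' @param X Leaf-state matrix (0/1), rows named by leaf, columns = OGs. A
#'   single column may be given as a named vector.
#' @return List with `sets` (integer matrix, nodes x OGs; bitmask 1 = state
#'   absent only, 2 = present only, 3 = ambiguous) and `score` (integer
#'   vector of parsimony scores per OG).
#' @export
fitch <- function(phy, X) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L, dimnames = list(names(X), "og"))
  idx <- tree_index(phy)
  if (!all(lengths(idx$children) %in% c(0L, 2L)))
    stop("fitch requires a binary tree; resolve polytomies first")
  if (anyNA(X) || !all(X %in% c(0L, 1L)))
    stop("leaf states must be 0/1 with no missing values")
  if (!setequal(rownames(X), phy$tip.label))
    stop("leaf-state rows must match tree leaves")
  X <- X[phy$tip.label, , drop = FALSE]
  m <- ncol(X)
  S <- matrix(0L, nrow = idx$nn, ncol = m)
  S[seq_len(idx$ntip), ] <- X + 1L
  score <- integer(m)
  for (v in idx$postorder) {
    ch <- idx$children[[v]]
    if (length(ch) == 2L) {
      a <- S[ch[1L], ]
      b <- S[ch[2L], ]
      iv <- bitwAnd(a, b)
      hit <- iv == 0L
      S[v, ] <- ifelse(hit, bitwOr(a, b), iv)
      score <- score + hit
    }
  }
  rownames(S) <- idx$labels
  colnames(S) <- colnames(X)
  list(sets = S, score = score)
}

#' ACCTRAN resolution of Fitch sets to node states
#'
#' Top-down pass assigning one state per node: the root takes its Fitch set's
#' single state, or the `root_tie` rule when the set is ambiguous; every other
#' node takes its parent's state when that state is in its Fitch set, else the
#' set's single state (placing each change on the highest possible branch).
#' The resulting labeling attains the parsimony score and never places
#' same-direction changes on both child branches of a node — the
#' precondition of the SEV contingency table.
#'
#' @param phy A binary rooted `phylo`.
#' @param fs Result of [fitch].
#' @param root_tie What an ambiguous root set resolves to: `"absent"`
#'   (state 0, default) or `"uncertain"` (`NA`; branches from an uncertain
#'   node then carry no counted change).
#' @return Integer matrix of states (0/1, `NA` = uncertain), nodes x OGs,
#'   rows named by node label (leaves first).
#' @export
acctran <- function(phy, fs, root_tie = c("absent", "uncertain")) {
  root_tie <- match.arg(root_tie)
  idx <- tree_index(phy)
  S <- fs$sets
  m <- ncol(S)
  A <- matrix(NA_integer_, nrow = idx$nn, ncol = m,
              dimnames = dimnames(S))
  rs <- S[idx$root, ]
  A[idx$root, ] <- ifelse(rs == 3L,
                          if (root_tie == "absent") 0L else NA_integer_,
                          rs - 1L)
  for (v in idx$preorder) {
    if (v == idx$root) next
    sv <- S[v, ]
    ap <- A[idx$parent[v], ]
    # parent state in the set -> inherit; else the set is a singleton
    inherit <- sv == 3L | (!is.na(ap) & bitwAnd(sv, ap + 1L) > 0L)
    A[v, ] <- ifelse(inherit, ap, sv - 1L)
    # ambiguous set under an uncertain parent stays uncertain
    amb <- sv == 3L & is.na(ap)
    if (any(amb)) A[v, amb] <- NA_integer_
  }
  A
}

#' Map node states to branch gain/loss events
#'
#' For every branch (indexed by its child node): `+1` if the OG is absent at
#' the parent and present at the child (gain), `-1` for the reverse (loss),
#' `0` otherwise. A branch touching an uncertain node carries no event: when
#' the ancestral state is uncertain, the change is regarded as not having
#' occurred on the branches extending from that node.
#'
#' @param phy A rooted `phylo`.
#' @param anc State matrix as returned by [acctran] or
#'   [read_ancestral_table] (nodes x OGs, `NA` = uncertain).
#' @return Integer matrix in `{-1, 0, 1}`, one row per non-root node (branch),
#'   rows named by child node label, in preorder.
#' @export
states_to_events <- function(phy, anc) {
  if (is.null(dim(anc))) anc <- matrix(anc, ncol = 1L,
                                       dimnames = list(names(anc), "og"))
  idx <- tree_index(phy)
  nonroot <- idx$preorder[idx$preorder != idx$root]
  E <- anc[nonroot, , drop = FALSE] - anc[idx$parent[nonroot], , drop = FALSE]
  E[is.na(E)] <- 0L
  storage.mode(E) <- "integer"
  rownames(E) <- idx$labels[nonroot]
  E
}

#' Parsimony ancestral states for every OG of a profile
#'
#' Convenience wrapper: [fitch] then [acctran] on each profile column.
#'
#' @param phy A binary rooted `phylo`.
#' @param profile Profile matrix (genomes x OGs).
#' @inheritParams acctran
#' @return Integer state matrix, nodes x OGs (see [acctran]).
#' @export
reconstruct_ancestral <- function(phy, profile, root_tie = "absent") {
  acctran(phy, fitch(phy, profile), root_tie = root_tie)
}
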