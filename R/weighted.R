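# Weighted (genome-counting) methods: naive, run-length encoding (RLE),
# clade-wise adjustment (CWA), and ancestral state adjustment (ASA).
# Each produces a 2x2 table of corrected genome counts per joint
# presence/absence state of an OG pair, which goes to Fisher's exact test.

# joint-state code: 2*x1 + x2, so 3="11", 2="10", 1="01", 0="00"; NA = U
joint_code <- function(x1, x2) 2L * x1 + x2

cell_names <- c("c11", "c10", "c01", "c00")

counts_from_codes <- function(codes, weights = NULL) {
  out <- c(c11 = 0, c10 = 0, c01 = 0, c00 = 0)
  if (is.null(weights)) weights <- rep(1, length(codes))
  for (s in 0:3) {
    nm <- cell_names[4L - s]
    out[nm] <- sum(weights[!is.na(codes) & codes == s])
  }
  out
}

#' Naive contingency counts for an OG pair
#'
#' Counts genomes by the joint presence/absence state of the two OGs; the
#' baseline method that cannot distinguish shared ancestry from repeated
#' co-gain/co-loss.
#'
#' @param x1,x2 Leaf-state vectors (0/1) for the two OGs, aligned to the same
#'   genomes.
#' @return Named numeric vector `c11, c10, c01, c00` summing to the number of
#'   genomes.
#' @export
naive_counts <- function(x1, x2) {
  stopifnot(length(x1) == length(x2))
  counts_from_codes(joint_code(x1, x2))
}

#' Run-length-encoded contingency counts
#'
#' Profiles are laid out in the tree's depth-first leaf order; consecutive
#' runs of identical joint states each count as one unit. Fast, but the
#' result depends on the drawn orientation of the tree: rotating a branch can
#' change the run structure.
#'
#' @param phy A rooted `phylo`.
#' @param x1,x2 Leaf-state vectors named by genome (0/1).
#' @return Named numeric vector of run counts per joint state.
#' @export
rle_counts <- function(phy, x1, x2) {
  ord <- leaf_order(phy)
  codes <- joint_code(x1[ord], x2[ord])
  counts_from_codes(rle(codes)$values)
}

#' Clade-wise adjusted contingency counts
#'
#' Each maximal clade whose leaves all share one joint state counts one unit;
#' leaves not in any such clade count one each. Invariant to branch rotation,
#' but paraphyletic groups sharing a state are not merged.
#'
#' @inheritParams rle_counts
#' @return Named numeric vector of clade counts per joint state.
#' @export
cwa_counts <- function(phy, x1, x2) {
  idx <- tree_index(phy)
  codes <- joint_code(x1[phy$tip.label], x2[phy$tip.label])
  pure <- rep(NA_integer_, idx$nn)  # joint state if the clade is uniform
  pure[seq_len(idx$ntip)] <- codes
  for (v in idx$postorder) {
    ch <- idx$children[[v]]
    if (length(ch) > 0L) {
      st <- pure[ch]
      if (!anyNA(st) && length(unique(st)) == 1L) pure[v] <- st[1L]
    }
  }
  is_block <- !is.na(pure) &
    (seq_len(idx$nn) == idx$root | is.na(pure[pmax(idx$parent, 1L)]) |
       idx$parent == 0L)
  counts_from_codes(pure[is_block])
}

#' Decompose a tree into same-state subtree blocks for ASA
#'
#' Given joint ancestral states for an OG pair at every node, each leaf is
#' traced back toward the root while every node on the path shares the leaf's
#' joint state; the highest node reached is the block root. Leaves sharing a
#' block root form one block (the "run" that ASA corrects). Uncertain nodes
#' (`NA`) break the trace.
#'
#' @param phy A rooted `phylo`.
#' @param js Integer vector of joint-state codes per node (ordered as
#'   [tree_index] labels: leaves then internal nodes), `NA` = uncertain.
#'   Leaf entries must not be `NA`.
#' @return A list of blocks, each with `root` (node index), `leaves` (integer
#'   leaf indices), `state` (joint-state code), and `M` (leaf count).
#' @export
asa_decompose <- function(phy, js) {
  idx <- tree_index(phy)
  if (anyNA(js[seq_len(idx$ntip)]))
    stop("leaf joint states must not be uncertain")
  comp <- integer(idx$nn)  # top node of the same-state run containing v
  for (v in idx$preorder) {
    p <- idx$parent[v]
    if (v == idx$root || is.na(js[v]) || is.na(js[p]) || js[v] != js[p]) {
      comp[v] <- v
    } else {
      comp[v] <- comp[p]
    }
  }
  tips <- seq_len(idx$ntip)
  groups <- split(tips, comp[tips])
  lapply(groups, function(lv) {
    list(root = comp[lv[1L]], leaves = lv, state = js[lv[1L]],
         M = length(lv))
  })
}

#' Branch-length-corrected genome count of a block
#'
#' Implements the ASA correction: for a block with `M` leaves,
#' `Mc = M * sum(b_n) / sum(b_n * l_n)` over the nodes `n` on the paths from
#' the block root to its member leaves, where `b_n` is the branch length
#' above `n` and `l_n` the number of member leaves at or below `n`. The
#' ratio equals total subtree time over the time of the equivalent star tree,
#' so `Mc` shrinks as shared (internal) time grows; a singleton block always
#' has `Mc = 1`.
#'
#' @param phy A rooted `phylo`.
#' @param block One block from [asa_decompose].
#' @param stem Include the block root's incoming branch in the sums
#'   (`"include"`, default) or not (`"exclude"`). The incoming branch of the
#'   tree root counts as length 0.
#' @return `Mc`, a positive real `<= M`. If every branch in the block has
#'   length 0 there is no time information and `Mc = M` with a warning.
#' @export
asa_correct <- function(phy, block, stem = c("include", "exclude")) {
  stem <- match.arg(stem)
  idx <- tree_index(phy)
  M <- block$M
  if (M == 1L && stem == "include") return(1)
  # l_n: member leaves at or below each node on the leaf->block-root paths
  l <- integer(idx$nn)
  on_path <- logical(idx$nn)
  for (leaf in block$leaves) {
    v <- leaf
    repeat {
      l[v] <- l[v] + 1L
      on_path[v] <- TRUE
      if (v == block$root) break
      v <- idx$parent[v]
    }
  }
  nodes <- which(on_path)
  b <- idx$blen[nodes]
  b[is.na(b)] <- 0  # tree root has no incoming branch
  if (stem == "exclude") {
    keep <- nodes != block$root
    if (!any(keep)) return(M)  # singleton: the leaf branch is the stem
    nodes <- nodes[keep]; b <- b[keep]
  }
  num <- sum(b)
  den <- sum(b * l[nodes])
  if (den == 0) {
    warning("block has no branch-length information; Mc = M")
    return(M)
  }
  M * num / den
}

#' Ancestral-state-adjusted contingency counts
#'
#' Decomposes the tree into same-joint-state blocks ([asa_decompose]), sums
#' the corrected counts `Mc` ([asa_correct]) per joint state (or counts each
#' block as one when `weighted = FALSE`), and rounds each of the four sums up
#' to an integer for Fisher's exact test.
#'
#' @param phy A rooted `phylo`.
#' @param anc1,anc2 Per-node state vectors for the two OGs (0/1/`NA`),
#'   ordered leaves-then-internals as produced by [acctran] columns or
#'   [read_ancestral_table]; leaf states must be 0/1.
#' @param weighted Apply the branch-length correction (default). `FALSE`
#'   gives the unweighted variant in which each subtree counts as one.
#' @inheritParams asa_correct
#' @return Named numeric vector `c11, c10, c01, c00` of (ceiled) corrected
#'   counts.
#' @export
asa_counts <- function(phy, anc1, anc2, weighted = TRUE,
                       stem = c("include", "exclude")) {
  stem <- match.arg(stem)
  js <- joint_code(anc1, anc2)  # NA if either OG uncertain at the node
  blocks <- asa_decompose(phy, js)
  states <- vapply(blocks, function(bl) as.numeric(bl$state), numeric(1))
  w <- if (weighted) {
    vapply(blocks, function(bl) asa_correct(phy, bl, stem = stem), numeric(1))
  } else {
    rep(1, length(blocks))
  }
  cells <- counts_from_codes(states, weights = w)
  # round each cell up; guard against floating-point noise on exact integers
  ceiling(round(cells, 9))
}
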