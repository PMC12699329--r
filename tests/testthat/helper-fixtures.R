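# Shared fixtures: small trees and random generators used across test files.

# random binary rooted tree with labeled internals and exp(1) branch lengths
random_tree <- function(n_leaves, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  phy <- ape::rtree(n_leaves, rooted = TRUE)
  phy$edge.length <- stats::rexp(nrow(phy$edge)) + 0.05
  phy$node.label <- NULL
  prepare_tree(phy)
}

# random 0/1 profile on the leaves of a tree
random_profile <- function(phy, m, p = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ntip <- length(phy$tip.label)
  matrix(as.integer(stats::runif(ntip * m) < p), nrow = ntip,
         dimnames = list(phy$tip.label, sprintf("og%03d", seq_len(m))))
}

# four-leaf balanced tree used throughout: ((A,B)N0,(C,D)N1)N2
balanced4 <- function() parse_newick("((A:1,B:1):1,(C:1,D:1):1);")

# exhaustive minimum-change count over all internal labelings (<= 8 leaves)
brute_force_parsimony <- function(phy, states) {
  idx <- tree_index(phy)
  internals <- which(lengths(idx$children) > 0L)
  full <- integer(idx$nn)
  full[seq_len(idx$ntip)] <- states[phy$tip.label]
  best <- Inf
  n_int <- length(internals)
  for (code in 0:(2^n_int - 1L)) {
    full[internals] <- bitwAnd(bitwShiftR(code, seq_len(n_int) - 1L), 1L)
    changes <- sum(full[idx$preorder[-1L]] !=
                     full[idx$parent[idx$preorder[-1L]]])
    if (changes < best) best <- changes
  }
  best
}

# independent per-pair concordance/discordance tally
tally_k <- function(u, v) {
  both <- u != 0L & v != 0L
  sum(both & u == v) - sum(both & u != v)
}

# hypergeometric tail from first principles (choose products)
enum_hyper_greater <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  x <- max(0, k - m2):min(m1, k)
  pr <- choose(m1, x) * choose(m2, k - x) / choose(m1 + m2, k)
  sum(pr[x >= a])
}

enum_hyper_two_sided <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  x <- max(0, k - m2):min(m1, k)
  pr <- choose(m1, x) * choose(m2, k - x) / choose(m1 + m2, k)
  pobs <- pr[x == a]
  sum(pr[pr <= pobs * (1 + 1e-7)])
}
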