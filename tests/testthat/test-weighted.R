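# Naive, RLE, CWA, and ASA contingency construction.

test_that("naive counts tally joint states and sum to the genome count", {
  expect_equal(naive_counts(c(1, 1, 0, 0), c(1, 1, 0, 0)),
               c(c11 = 2, c10 = 0, c01 = 0, c00 = 2))
  expect_equal(naive_counts(c(1, 0, 1, 0), c(0, 1, 0, 1)),
               c(c11 = 0, c10 = 2, c01 = 2, c00 = 0))
  set.seed(21)
  x1 <- sample(0:1, 50, replace = TRUE)
  x2 <- sample(0:1, 50, replace = TRUE)
  nc <- naive_counts(x1, x2)
  brute <- c(c11 = 0, c10 = 0, c01 = 0, c00 = 0)
  for (i in 1:50) {  # independent loop tally
    cell <- paste0("c", x1[i], x2[i])
    brute[cell] <- brute[cell] + 1
  }
  expect_equal(nc, brute)
  expect_equal(sum(nc), 50)
})

test_that("rle counts collapse runs along the leaf order", {
  tr <- parse_newick("((((A:1,B:1):1,C:1):1,D:1):1,E:1);")
  # leaf order A,B,C,D,E; give joint states 11,11,00,00,11
  x1 <- c(A = 1, B = 1, C = 0, D = 0, E = 1)
  expect_equal(rle_counts(tr, x1, x1),
               c(c11 = 2, c10 = 0, c01 = 0, c00 = 1))
  allsame <- c(A = 1, B = 1, C = 1, D = 1, E = 1)
  expect_equal(rle_counts(tr, allsame, allsame),
               c(c11 = 1, c10 = 0, c01 = 0, c00 = 0))
})

test_that("rle depends on rotation where cwa does not (6-leaf witness)", {
  tr <- parse_newick("((A:1,B:1):1,((C:1,D:1):1,(E:1,F:1):1):1);")
  # two 11 clades separated by a 00 clade in leaf order A,B,C,D,E,F
  x1 <- c(A = 1, B = 1, C = 0, D = 0, E = 1, F = 1)
  x2 <- x1
  base_rle <- rle_counts(tr, x1, x2)
  expect_equal(base_rle, c(c11 = 2, c10 = 0, c01 = 0, c00 = 1))
  # rotate the node separating (C,D) and (E,F): 11 clades become adjacent
  idx <- coevotree:::tree_index(tr)
  target <- idx$labels[idx$parent[which(idx$labels == "C")]]
  parent_cd_ef <- idx$labels[idx$parent[match(target, idx$labels)]]
  rot <- rotate_node(tr, parent_cd_ef)
  expect_equal(leaf_order(rot), c("A", "B", "E", "F", "C", "D"))
  rot_rle <- rle_counts(rot, x1, x2)
  expect_equal(rot_rle, c(c11 = 1, c10 = 0, c01 = 0, c00 = 1))
  expect_false(identical(base_rle, rot_rle))
  expect_identical(cwa_counts(tr, x1, x2), cwa_counts(rot, x1, x2))
})

test_that("cwa merges monophyletic blocks only", {
  tr <- balanced4()
  x1 <- c(A = 1, B = 1, C = 1, D = 0)
  x2 <- c(A = 1, B = 1, C = 0, D = 0)
  # A=B=11 (cherry, merges), C=10, D=00
  expect_equal(cwa_counts(tr, x1, x2),
               c(c11 = 1, c10 = 1, c01 = 0, c00 = 1))
  ones <- c(A = 1, B = 1, C = 1, D = 1)
  expect_equal(cwa_counts(tr, ones, ones),
               c(c11 = 1, c10 = 0, c01 = 0, c00 = 0))
  # paraphyletic same-state leaves straddling the root are NOT merged
  x3 <- c(A = 1, B = 0, C = 0, D = 1)
  expect_equal(cwa_counts(tr, x3, x3),
               c(c11 = 2, c10 = 0, c01 = 0, c00 = 2))
})

test_that("asa decomposition traces blocks through same-state ancestors", {
  tr <- balanced4()
  labs <- coevotree:::tree_index(tr)$labels
  # internal-left 11, internal-right 00, root uncertain
  anc1 <- stats::setNames(c(1L, 1L, 0L, 0L, NA, 1L, 0L), labs)
  anc2 <- anc1
  js <- coevotree:::joint_code(anc1, anc2)
  blocks <- asa_decompose(tr, js)
  expect_length(blocks, 2L)
  expect_setequal(vapply(blocks, `[[`, numeric(1), "M"), c(2, 2))
  # all nodes share state 11: one block rooted at the tree root
  all1 <- stats::setNames(rep(1L, 7), labs)
  js1 <- coevotree:::joint_code(all1, all1)
  b1 <- asa_decompose(tr, js1)
  expect_length(b1, 1L)
  expect_equal(b1[[1]]$M, 4)
  expect_equal(b1[[1]]$root, coevotree:::tree_index(tr)$root)
})

test_that("asa correction follows the subtree/star-tree ratio", {
  # singleton block: Mc = 1 regardless of branch length
  tr <- parse_newick("((A:1,B:1):1,C:5);")
  idx <- coevotree:::tree_index(tr)
  labs <- idx$labels
  # cherry (A,B) present, C and the root absent: block root = cherry node
  anc <- stats::setNames(integer(5), labs)
  anc[c("A", "B", labs[setdiff(which(lengths(idx$children) > 0), idx$root)])] <- 1L
  js <- coevotree:::joint_code(anc, anc)
  blocks <- asa_decompose(tr, js)
  singleton <- blocks[[which(vapply(blocks, `[[`, numeric(1), "M") == 1)]]
  expect_equal(asa_correct(tr, singleton), 1)
  # cherry with stem 0 and unit legs: Mc = 2 (no shared time)
  tr0 <- parse_newick("((A:1,B:1):0,C:5);")
  b0 <- asa_decompose(tr0, js)
  cherry0 <- b0[[which(vapply(b0, `[[`, numeric(1), "M") == 2)]]
  expect_equal(asa_correct(tr0, cherry0), 2)
  # cherry with stem 1 and unit legs: Mc = 2*(1+1+1)/(2+1+1) = 1.5
  cherry1 <- blocks[[which(vapply(blocks, `[[`, numeric(1), "M") == 2)]]
  expect_equal(asa_correct(tr, cherry1), 1.5)
  # excluding the stem removes the correction for a bare cherry
  expect_equal(asa_correct(tr, cherry1, stem = "exclude"), 2)
})

test_that("Mc is scale-free overall but shrinks as internal lengths grow", {
  tr <- random_tree(16, seed = 77)
  labs <- coevotree:::tree_index(tr)$labels
  ntip <- 16L
  anc <- stats::setNames(rep(1L, length(labs)), labs)
  js <- coevotree:::joint_code(anc, anc)
  block <- asa_decompose(tr, js)[[1]]
  mc0 <- asa_correct(tr, block)
  expect_lte(mc0, block$M)
  # uniform scaling leaves Mc unchanged
  sc <- tr; sc$edge.length <- sc$edge.length * 7.3
  expect_equal(asa_correct(sc, asa_decompose(sc, js)[[1]]), mc0,
               tolerance = 1e-10)
  # scaling only internal branches strictly decreases Mc
  up <- tr
  internal_edges <- up$edge[, 2] > ntip
  up$edge.length[internal_edges] <- up$edge.length[internal_edges] * 3
  expect_lt(asa_correct(up, asa_decompose(up, js)[[1]]), mc0)
})

test_that("asa counts apply the per-cell ceiling and block counting", {
  # cells from stated blocks: {11: 2.3, 1.0}, {00: 5.5}, {10: 0.2}
  w <- c(2.3, 1.0, 5.5, 0.2)
  st <- c(3, 3, 0, 2)
  cells <- coevotree:::counts_from_codes(st, weights = w)
  expect_equal(ceiling(round(cells, 9)),
               c(c11 = 4, c10 = 1, c01 = 0, c00 = 6))
  expect_equal(coevotree:::counts_from_codes(st),
               c(c11 = 2, c10 = 1, c01 = 0, c00 = 1))
})

test_that("asa on a star tree equals naive counts", {
  set.seed(55)
  n <- 12
  nwk <- paste0("(", paste0(letters[1:n], ":",
                            round(stats::runif(n, 0.5, 2), 3),
                            collapse = ","), ");")
  star <- parse_newick(nwk, resolve = FALSE)
  labs <- coevotree:::tree_index(star)$labels
  for (rep in 1:10) {
    x1 <- stats::setNames(sample(0:1, n, replace = TRUE), letters[1:n])
    x2 <- stats::setNames(sample(0:1, n, replace = TRUE), letters[1:n])
    anc1 <- c(x1, stats::setNames(sample(0:1, 1), labs[n + 1]))
    anc2 <- c(x2, stats::setNames(sample(0:1, 1), labs[n + 1]))
    expect_equal(asa_counts(star, anc1, anc2, weighted = TRUE),
                 naive_counts(x1, x2))
  }
})

test_that("compression never exceeds naive counts cell-wise", {
  set.seed(66)
  for (rep in 1:10) {
    tr <- random_tree(20)
    X <- random_profile(tr, 2)
    x1 <- X[, 1]; x2 <- X[, 2]
    nv <- naive_counts(x1, x2)
    expect_true(all(cwa_counts(tr, x1, x2) <= nv))
    anc <- reconstruct_ancestral(tr, X)
    expect_true(all(asa_counts(tr, anc[, 1], anc[, 2]) <= nv))
    expect_true(all(rle_counts(tr, x1, x2) <= nv))
  }
})
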