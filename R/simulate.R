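# Coevolution simulator: Yule species trees and an interacting two-OG
# binary-trait Markov chain, used to generate labeled test datasets in which
# a known fraction of OG pairs truly co-evolve.

#' Simulate a Yule (pure-birth) species tree
#'
#' @param n_leaves Number of extant leaves (>= 2).
#' @param birth_rate Speciation rate (per unit time).
#' @param seed Optional integer seed for reproducibility.
#' @return A prepared binary rooted ultrametric `phylo` with labeled
#'   internal nodes.
#' @export
yule_tree <- function(n_leaves, birth_rate = 1, seed = NULL) {
  stopifnot(n_leaves >= 2)
  if (!is.null(seed)) set.seed(seed)
  phy <- phytools::pbtree(b = birth_rate, n = n_leaves, quiet = TRUE)
  prepare_tree(phy)
}

#' Simulate one interacting OG pair on a tree
#'
#' Joint continuous-time Markov chain over the four presence/absence states
#' of two OGs, evolved root-to-tips with exact event-time (Gillespie)
#' sampling on every branch. Instantaneous per-OG rates given the partner's
#' current state `x_partner`:
#' \deqn{gain_i = exp(alpha_i + beta_i + c \cdot x_{partner}),\quad
#'       loss_i = exp(alpha_i - beta_i - c \cdot x_{partner})}
#' so `alpha` sets the overall rate, `beta` is half the log gain/loss
#' asymmetry, and the interaction coefficient `c > 0` makes presence of one
#' OG favor gain (and disfavor loss) of the other; `c = 0` is the
#' independent null. The root state is drawn per OG from the stationary
#' distribution of its own chain at partner state 0 (or uniformly with
#' `root_state = "uniform"`).
#'
#' @param phy A rooted `phylo` with branch lengths.
#' @param c_coef Interaction coefficient.
#' @param alpha,beta Length-2 numeric vectors: intrinsic rate and gain/loss
#'   asymmetry parameters of the two OGs (scalars recycle).
#' @param root_state `"stationary"` (default) or `"uniform"`.
#' @return Integer matrix with one row per leaf (named) and two columns.
#' @export
simulate_pair <- function(phy, c_coef = 0, alpha = 0, beta = 0,
                          root_state = c("stationary", "uniform")) {
  root_state <- match.arg(root_state)
  alpha <- rep_len(alpha, 2L)
  beta <- rep_len(beta, 2L)
  rates <- function(x, i) {
    xp <- x[3L - i]
    g <- exp(alpha[i] + beta[i] + c_coef * xp)
    l <- exp(alpha[i] - beta[i] - c_coef * xp)
    if (!is.finite(g) || !is.finite(l)) stop("non-finite transition rate")
    if (x[i] == 0L) g else l  # rate of flipping OG i
  }
  idx <- tree_index(phy)
  state <- matrix(0L, nrow = idx$nn, ncol = 2L)
  x0 <- integer(2L)
  for (i in 1:2) {
    if (root_state == "uniform") {
      x0[i] <- as.integer(stats::runif(1) < 0.5)
    } else {
      g <- exp(alpha[i] + beta[i])
      l <- exp(alpha[i] - beta[i])
      x0[i] <- as.integer(stats::runif(1) < g / (g + l))
    }
  }
  state[idx$root, ] <- x0
  for (v in idx$preorder) {
    if (v == idx$root) next
    x <- state[idx$parent[v], ]
    t_left <- idx$blen[v]
    repeat {
      r1 <- rates(x, 1L)
      r2 <- rates(x, 2L)
      dt <- stats::rexp(1, r1 + r2)
      if (dt > t_left) break
      t_left <- t_left - dt
      flip <- if (stats::runif(1) < r1 / (r1 + r2)) 1L else 2L
      x[flip] <- 1L - x[flip]
    }
    state[v, ] <- x
  }
  out <- state[seq_len(idx$ntip), , drop = FALSE]
  rownames(out) <- phy$tip.label
  out
}

#' Generate a labeled coevolution dataset
#'
#' Emulates the standard benchmark protocol: OG pairs are simulated
#' independently on one tree and concatenated into a single profile. A
#' fraction of pairs are true positives with interaction coefficient
#' `c ~ U(0.2, 0.75)`; the rest have `c = 0`. Per OG, intrinsic rates
#' `alpha ~ U(-0.5, 1)` and asymmetries `beta ~ U(-0.5, 0.3)`. Defaults are
#' the benchmark's parameter distributions, with positives:negatives 1:99.
#'
#' @param phy A rooted `phylo` with branch lengths.
#' @param n_pairs Number of OG pairs to simulate.
#' @param positive_fraction Fraction of pairs that truly co-evolve
#'   (default 0.01).
#' @param seed Optional integer seed.
#' @param c_range,alpha_range,beta_range Uniform sampling ranges.
#' @return List with `profile` (leaves x `2 n_pairs` matrix, columns
#'   `OG<i>a`/`OG<i>b`), `truth` (data frame `og1`, `og2`, `coevolved`,
#'   `c_coef`), and `params` (per-pair parameter data frame).
#' @export
generate_dataset <- function(phy, n_pairs, positive_fraction = 0.01,
                             seed = NULL, c_range = c(0.2, 0.75),
                             alpha_range = c(-0.5, 1),
                             beta_range = c(-0.5, 0.3)) {
  stopifnot(n_pairs >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_pos <- round(n_pairs * positive_fraction)
  pos <- sort(sample.int(n_pairs, n_pos))
  og1 <- sprintf("OG%04da", seq_len(n_pairs))
  og2 <- sprintf("OG%04db", seq_len(n_pairs))
  cc <- numeric(n_pairs)
  cc[pos] <- stats::runif(n_pos, c_range[1L], c_range[2L])
  a1 <- stats::runif(n_pairs, alpha_range[1L], alpha_range[2L])
  a2 <- stats::runif(n_pairs, alpha_range[1L], alpha_range[2L])
  b1 <- stats::runif(n_pairs, beta_range[1L], beta_range[2L])
  b2 <- stats::runif(n_pairs, beta_range[1L], beta_range[2L])
  ntip <- length(phy$tip.label)
  profile <- matrix(0L, nrow = ntip, ncol = 2L * n_pairs,
                    dimnames = list(phy$tip.label,
                                    as.vector(rbind(og1, og2))))
  for (i in seq_len(n_pairs)) {
    xy <- simulate_pair(phy, c_coef = cc[i], alpha = c(a1[i], a2[i]),
                        beta = c(b1[i], b2[i]))
    profile[, 2L * i - 1L] <- xy[phy$tip.label, 1L]
    profile[, 2L * i] <- xy[phy$tip.label, 2L]
  }
  truth <- data.frame(og1 = og1, og2 = og2,
                      coevolved = seq_len(n_pairs) %in% pos,
                      c_coef = cc, stringsAsFactors = FALSE)
  params <- data.frame(og1 = og1, og2 = og2, c_coef = cc,
                       alpha1 = a1, alpha2 = a2, beta1 = b1, beta2 = b2,
                       stringsAsFactors = FALSE)
  list(profile = profile, truth = truth, params = params)
}
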