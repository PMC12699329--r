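---
title: "Scoring gene co-evolution on species trees: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring gene co-evolution on species trees: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevotree)
```

## The problem

Phylogenetic profiling infers functional links between ortholog groups
(OGs) from the pattern of their presence and absence across genomes: OGs
that are gained and lost together are likely to work together, and OGs
that avoid each other ("contrapositive" pairs) often encode alternative
solutions to the same problem. The central statistical difficulty is shared
ancestry. A pair of OGs inherited once from a common ancestor co-occurs in
every descendant genome, producing the same 2x2 contingency table as a pair
that was co-gained repeatedly in independent lineages — yet only the second
pattern is evidence of co-evolution. Every method in this package is a
different answer to the question: *how should genomes be counted, or
events be counted, so that shared history is not mistaken for repeated,
independent co-occurrence?*

The package scores all (or selected) OG pairs from two inputs: a rooted
species tree with branch lengths and a binary genomes x OGs profile
matrix. Two of the methods additionally use ancestral presence/absence
states at the internal nodes, reconstructed internally by parsimony or
supplied as an external table (e.g. from a maximum-likelihood marginal
reconstruction).

## Weighted methods: correcting the genome count

The **naive** method counts genomes per joint state of the pair —
`c11, c10, c01, c00` — and applies Fisher's exact test. It is the baseline
that cannot see history.

**RLE** (run-length encoding) lays the profiles out in the depth-first leaf
order of the tree and counts each run of consecutive identical joint states
as one. It is fast but *orientation-dependent*: rotating the children of an
internal node changes nothing about the tree topology, yet changes the leaf
order and hence the runs.

**CWA** (clade-wise adjustment) counts each maximal monophyletic clade of
identical joint state as one. It is rotation-invariant, but cannot merge
paraphyletic groups that inherited their state from a single ancestor.

**ASA** (ancestral state adjustment) uses the reconstructed ancestral joint
states to partition the tree into *blocks*: starting from each leaf, walk
rootward while every node on the path has the same joint state as the leaf
(stopping before any node whose state differs or is uncertain); leaves
reaching the same highest node form one block. The genome count `M` of a
block is then corrected by evolutionary time:

$$ M_C \;=\; M \times
   \frac{\sum_{n \in N} b_n}{\sum_{n \in N} b_n\, l_n} $$

where `N` is the set of nodes on the paths from the block root to its
member leaves (including the block root), `b_n` is the branch length above
node `n`, and `l_n` the number of member leaves at or below `n`. The
numerator is the total branch length of the block's subtree; the
denominator is the branch length of the star tree obtained by giving each
member leaf its own independent path — i.e. the time the members *would*
have evolved had they been independent. Deep, long-stemmed blocks are
therefore compressed strongly, while a star-like block keeps `M_C = M`
(on a pure star tree weighted ASA reduces exactly to the naive count). Per
pair, the four per-joint-state sums of `M_C` are rounded **up** to integers
before Fisher's exact test. The unweighted variant counts each block as
one, like CWA but on ancestral-state blocks.

Two points were genuinely open and are package design choices:

* **The block root's stem branch enters the sums.** The stated equivalence
  between the denominator and a star tree only balances when the shared
  stem — the time on which the block's state arose — appears in both sums;
  excluding it would leave a bare cherry completely uncorrected. A flag
  (`asa_stem = "exclude"`) exposes the alternative.
* **The ceiling is applied per cell**, not to the grand total, because the
  exact test needs four integers; and Fisher's test for the weighted
  methods is **two-sided** by default (both co-occurrence and avoidance are
  of interest), with `alternative = "greater"` available.

## Transition methods: counting events instead of genomes

**Cotransitions** orders the profiles along the tree's leaf order and marks
each gap between adjacent genomes with +1 (0 to 1), -1 (1 to 0) or 0 per
OG. **SEV** (simultaneous evolution test) instead maps gains and losses
onto the *branches* of the tree from reconstructed ancestral states: +1
when an OG is absent at a parent and present at its child, -1 for the
reverse, 0 otherwise, and — whenever either endpoint of a branch is
uncertain — the change is regarded as not having occurred on that branch.

For both methods the score of a pair is
`k = concordances - discordances`: the number of rows (gaps or branches)
where both OGs change in the same direction minus those where they oppose.
Collecting all OG event vectors into a single matrix `E` in `{-1, 0, +1}`
gives every pairwise score at once as `K = t(E) %*% E` — one integer matrix
product, which is what makes these methods practical for tens of thousands
of OGs. With `t1`, `t2` the per-OG event counts, the pair is tested
one-tailed on the table

|          |            |
|----------|------------|
| \|k\|    | t1 - \|k\| |
| t2 - \|k\| | n - t1 - t2 + \|k\| |

with `p = P(X >= |k|)` for hypergeometric `X`, and the sign of `k` gives
the direction (positive = co-evolved, negative = contrapositive). The
population size `n` is the number of **internal nodes** for SEV — not the
number of branches, because a parsimony reconstruction never places the
same gain (or loss) on both child branches of one node, so at most one
change per OG can be attributed to each internal node — and `genomes - 1`
for cotransitions, where changes live between adjacent genomes.

Ancestral states for SEV come from Fitch parsimony resolved ACCTRAN-style
(top-down, each node inheriting its parent's state whenever that state is
in its Fitch set), which attains the parsimony score and guarantees the
no-parallel-change constraint. Design choices here:

* **Ambiguous root sets resolve to absence** (`root_tie = "absent"`) by
  default; determinism matters more than the direction of the tie, and
  `root_tie = "uncertain"` reproduces the convention in which branches from
  an uncertain root carry no counted change.
* **External state tables** (e.g. ML marginal reconstructions) can violate
  the no-parallel-change constraint; `sev_events` checks and refuses them
  with the offending node and OG named. If a user-supplied reconstruction
  still yields a table outside hypergeometric support
  (`n - t1 - t2 + |k| < 0`), the pair gets the p-value of the most extreme
  supported table (1) and an `out_of_support` flag rather than an error.
* **Concordance is strictly same-branch.** Opposite-direction changes of
  the two OGs on the two sibling branches of one node are *not* counted as
  discordance; this is the matrix-product definition, and the alternative
  would forfeit the single-product scalability.
* **Cotransitions** is implemented in its plain matrix form by default; the
  historical behavior in which a change immediately following another
  change of the same OG is ignored is available as
  `collapse_consecutive = TRUE` (the first change of each adjacent run is
  kept).

## Rotation invariance

Branch rotation — reversing the child order of an internal node — changes
the drawn tree but not the phylogeny. Naive, CWA, ASA and SEV are exactly
invariant under rotation (asserted bitwise in the test suite over random
rotation sequences); RLE and cotransitions are not, which is their
fundamental defect: the same data in a different orientation yields
different contingency tables. A six-leaf witness (two same-state clades
adjacent in one orientation, separated in another) demonstrates the
inequality in the tests.

## The simulator

`yule_tree` grows a pure-birth tree (via `phytools::pbtree`, one lineage
growing at rate `b` until `n` tips). `simulate_pair` evolves a pair of
binary traits root-to-tips as a joint 4-state continuous-time Markov chain
with exact event-time sampling on every branch; per-OG rates given the
partner's current state are

    gain_i = exp(alpha_i + beta_i + c * x_partner)
    loss_i = exp(alpha_i - beta_i - c * x_partner)

so `alpha` sets the overall rate, `beta` is half the log gain/loss
difference, and `c` couples the pair (`c = 0` is the independent null; the
root state is drawn from the per-OG stationary distribution at partner
state 0). This is an "evolCCM-like" parameterization: it preserves the
published roles of the five parameters per pair without claiming numerical
equivalence to any particular implementation. `generate_dataset`
concatenates independently simulated pairs into one profile, marking a
fraction of pairs (default 1%) as positives with `c ~ U(0.2, 0.75)` and
sampling `alpha ~ U(-0.5, 1)`, `beta ~ U(-0.5, 0.3)` per OG — the
benchmark distributions.

**What the simulator does and does not emulate.** It reproduces the
tree-shaped dependence structure, gain/loss asymmetry, rate variation
across OGs, and a tunable interaction — enough to test every code path and
the calibration of the null. It does *not* emulate horizontal transfer,
lineage-specific rate shifts, genome-quality noise, or annotation error.
One consequence deserves emphasis: under the simulated null (`c = 0`) the
two OGs are *truly independent given the tree*, so the naive method's
real-world failure mode — confounding by shared ancestry — is only mildly
present, and at these parameter settings profiles are fast-evolving
(median parsimony event counts above 100 on a 500-leaf tree), a regime in
which same-branch co-transitions from a coupling of `c <= 0.75` barely
exceed their chance expectation. Synthetic benchmarks built from this
protocol therefore flatter the naive method and understate the transition
methods, and passing or failing a synthetic ranking comparison says little
about performance on real, slowly-evolving, ancestrally-confounded
profiles. The test suite asserts the mechanical properties (calibration of
the null, rotation invariance, oracle equality) rather than real-data
orderings.

## Numerical and degenerate-input choices

* Exact tests use the hypergeometric distribution directly (log-space pmf
  via `stats::dhyper`/`phyper`); the two-sided rule sums all tables with
  point probability at most the observed one times `1 + 1e-7`.
* Ceiled ASA cells are rounded to 9 decimals before the ceiling so that
  sums that are integers up to floating-point noise are not inflated.
* Missing branch lengths default to 1 with a warning (ASA needs lengths;
  SEV does not use them). An ASA block whose branches are all zero-length
  carries no time information and falls back to `Mc = M` with a warning.
* Polytomies are resolved to binary by left-folding children in stored
  order with zero-length stems: leaf-to-leaf path lengths are unchanged,
  ASA's sums are unperturbed, and SEV's internal-node count convention
  becomes well-defined. Trees are used as rooted exactly as given.
* Unlabeled internal nodes are named `N0, N1, ...` by postorder index, so
  external ancestral tables can be regenerated reproducibly.
* Prevalence filtering (`prevalence_filter`, default 1%–99% inclusive)
  removes OGs whose near-fixation or near-absence makes their pair
  statistics uninformative.

## Problem sizes used by the tests

The packaged checks run at desk scale, chosen so the full suite completes
in minutes: oracle comparisons on 50 x 200 event matrices and all 2x2
tables with `N <= 30`; exhaustive parsimony enumeration on trees of up to
8 leaves (500 random columns); rotation invariance on a 64-leaf tree over
50 random rotation sequences; and a simulated screen of 200 pairs on a
500-leaf Yule tree with a 1:19 positive:negative ratio over 5 seeds.
`scripts/acceptance.R` re-runs the simulated screen end to end and reports
per-method PRAUC and detected-positive counts.

## Known limitations

* Parsimony underestimates event counts on fast-evolving OGs; SEV inherits
  that bias (it is also why `t <= n` always holds internally).
* The ACCTRAN root tie rule is a convention; results for OGs whose root
  state is genuinely ambiguous depend on it (only through events on the
  root's child branches).
* Weighted-method p-values treat corrected counts as if they were genome
  counts; the ceiling makes them conservative in small tables but the test
  is still approximate in spirit.
* All-pairs scoring for the weighted methods loops over pairs in R and is
  intended for thousands, not millions, of pairs; the transition methods
  scale via the matrix product.
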