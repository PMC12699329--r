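Package: coevotree
Title: Phylogenetic Profiling of Gene Co-Evolution with Ancestral States
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores pairs of ortholog groups (OGs) for co-evolution or
    contrapositive (mutually avoiding) evolution from a rooted species tree
    and a binary presence/absence profile matrix. Implements six
    phylogenetic-profiling methods: naive genome counting, run-length
    encoding (RLE), clade-wise adjustment (CWA), ancestral state adjustment
    (ASA, with and without branch-length correction), cotransitions, and
    the simultaneous evolution test (SEV). SEV and ASA use reconstructed
    ancestral presence/absence states (internal Fitch/ACCTRAN parsimony or
    an external table); all-versus-all event concordance is computed by
    matrix multiplication. Includes a coevolution simulator (Yule trees
    with an interacting two-trait Markov model) and precision-recall
    evaluation utilities.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phytools,
    stats,
    utils
Suggests:
    phangorn,
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
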