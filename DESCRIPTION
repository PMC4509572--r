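Package: barcodeval
Title: Evaluation of Multi-Locus DNA Barcodes for Tree Species Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate how well a multi-locus DNA barcode reference
    library (e.g. rbcL, matK, trnH-psbA and ITS for a plot-based tree flora)
    discriminates species. Builds partitioned supermatrices from per-locus
    alignments (including block-diagonal per-family alignments for loci that
    cannot be globally aligned), computes p and K2P distances with pairwise
    deletion, reconstructs Neighbor-Joining trees with nonparametric bootstrap
    support, scores species/genus/family discrimination by supported
    monophyly, performs similarity-based identification under a >=95 percent
    identity plus conspecific-dominance rule (leave-one-out and cross-plot
    reference-database designs), flags specimens whose tree placement
    conflicts with their recorded taxonomy, and ships a synthetic
    barcode-data generator (nested taxonomy, JC69 divergence, per-locus
    sequence recovery, injectable field misidentifications) so the whole
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
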