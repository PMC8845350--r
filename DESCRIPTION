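Package: clonescreen
Title: Clone Detection and Clone-Aware Analysis for Single-Cell CRISPR Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies clonally expanded cells in high-MOI single-cell CRISPR
    screens by treating each cell's multiplexed sgRNA complement as a clonal
    barcode. Provides a log-space hypergeometric test of sgRNA overlap, an
    agglomerative clone-grouping algorithm with inline doublet flagging,
    per-cell guide UMI saturation-curve (knee) filtering, simulators for guide
    populations with planted clones, doublets and segmental copy-number
    changes, a power analysis of clone detectability over library size and
    guides per cell, relative copy-number profiling from chromosomally ordered
    expression z-scores, and region-level differential-expression significance
    scores computed against randomized sgRNA-combination backgrounds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    mclust,
    yaml,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
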