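Package: lmrsvm
Title: Enhancer Prediction from Low-Methylated Regions with a Weighted
    Support Vector Machine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Learns cell-type-specific enhancer classifiers from the DNA
    sequence of low-methylated regions (LMRs) called from whole-genome
    bisulfite sequencing.  LMRs are encoded as normalized k-mer count
    vectors, ranked by a kernel density estimate fitted on the subset that
    overlaps validated enhancers, and partitioned into reliable-positive,
    likely-positive and likely-negative sets.  Together with an
    exclusion-aware shuffled background set, a four-weight soft-margin
    linear support vector machine is trained and selected by
    cross-validated F-score, precision and a genomic-coverage constraint.
    The fitted model scans a genome with sliding windows, merges positive
    windows into enhancers, and validates them against DNase, p300,
    transcription-factor, CAGE-enhancer and conservation tracks.  A seeded
    simulator of toy genomes with planted enhancers supports end-to-end
    testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    e1071,
    kernlab,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
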