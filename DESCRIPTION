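Package: schickit
Title: Single-Cell Hi-C Contact Classification, Cell Calling, and
    Chromatin-State Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for downstream analysis of
    barcode-tagged single-cell Hi-C contact data. Provides a seeded
    two-species toy-genome simulator with planted artifact categories,
    doublets and chromatin states; GATC-avoiding combinatorial barcode
    whitelists and demultiplexing; restriction-fragment assignment and
    HiC-Pro-convention pair classification with per-cell quality control;
    barcode-rank knee-point cell calling and barnyard collision-rate
    estimation; sparse contact binning with iterative correction,
    distance-decay curves, library-complexity saturation fits, coverage
    metrics and aggregate peak analysis; multi-window insulation scores
    with boundary calls and A/B compartment eigenvectors; melting and
    concretion chromatin-state detection with a one-sided
    Kolmogorov-Smirnov melting score; and in silico cell phasing via
    replication-timing and sex-chromosome haploid scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    Biostrings,
    mclust,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
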