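Package: cistromer
Title: Integrative Analysis of Transcription-Factor Cistromes, Expression
    Dynamics and Tumor-Initiating Cell Frequency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative ChIP-seq/RNA-seq analysis toolkit for dissecting
    how a transcription factor reprograms a cancer cell state. Provides
    summit-anchored peak annotation against gene models, multi-factor
    cistrome co-occupancy classification and genome-binned occupancy
    correlation, peak-centered signal matrices and non-promoter histone
    profiles, exact position-weight-matrix score calibration with central
    motif enrichment statistics, a conditional negative-binomial exact test
    with fold-change/p-value differential-expression calls and trajectory
    clustering into archetypes, Fisher exact peak-to-cluster enrichment,
    and single-hit Poisson estimation of tumor-initiating cell frequency
    from limiting-dilution assays. A synthetic-data module generates every
    input with planted ground truth so the whole pipeline is testable
    end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    edgeR,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
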