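Package: velocitt
Title: Elongation-Velocity Analysis of Nascent Transcription (TT-seq / mNET-seq)
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate RNA polymerase II elongation velocity from paired
    TT-seq (nascent RNA synthesis) and mNET-seq (engaged-polymerase occupancy)
    sequencing data. Implements spike-in and non-transcribed-region
    median-of-ratios normalization, strand-specific gene counting with
    IntersectionNotEmpty disambiguation, the per-bin and per-gene TT-seq/mNET-seq
    velocity ratio statistic, bootstrap metagene profiles, TSS- and
    gene-center-aligned change heatmap matrices, and figure-legend statistics
    (Wilcoxon tests, notched-boxplot summaries, MA values). A stochastic
    polymerase-trajectory simulator with known ground truth generates synthetic
    TT-seq, mNET-seq, ChIP-seq and spike-in data so that every stage of the
    pipeline is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    DESeq2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
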