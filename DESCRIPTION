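Package: thermoseq
Title: Two-Temperature Rice Transcriptome Quantification, Fold-Change and
    Binomial Enrichment Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tidyverse-native pipeline for two-condition bulk RNA-seq
    without replicates, modelled on genome-wide expression profiling of rice
    leaf blades grown at 25 and 30 degrees Celsius. Quantifies gene
    expression as RPKM from multimapper-weighted read counts (SAM NH tags),
    computes median-pseudocount-stabilised fold changes with regulation
    bins, and scores over-representation of GO, KEGG and
    transcription-factor-family gene sets among regulated genes with an
    exact one-sided binomial tail test. Includes a synthetic-study
    generator with planted differential expression and planted category
    enrichment so every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicAlignments,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
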