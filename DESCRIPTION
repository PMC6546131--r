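Package: methlink
Title: Reconstruct Altered Gene Regulatory Networks from Paired DNA
    Methylation and Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links distal cis-regulatory elements to target genes from
    matched DNA methylation (array beta values) and gene expression
    matrices. Calls differentially methylated distal CpG probes in a
    supervised (predefined two-group) or unsupervised (per-locus extreme
    quantile) mode, pairs them with nearby genes through
    methylation/expression anti-correlation backed by a permutation
    empirical p-value, tests transcription factor binding motifs for
    enrichment around the linked probes with Fisher's exact test and
    odds-ratio confidence intervals, ranks candidate master regulator
    transcription factors by the association of their expression with
    motif-flanking methylation, annotates results with cell-type
    chromatin states, and clusters master regulators across analyses.
    Ships a synthetic cohort generator with planted, recoverable signal
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    GenomicRanges,
    generics,
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
    jsonlite,
    knitr,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
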