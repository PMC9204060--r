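Package: cernaforge
Title: Competing Endogenous RNA Network Inference from Whole-Transcriptome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for lncRNA-miRNA-mRNA competing
    endogenous RNA (ceRNA) inference in bulk RNA-seq studies, modelled on
    whole-transcriptome analyses of plant early senescence. Provides
    FPKM/TPM normalisation and a documented differential-expression
    surrogate (Welch's t on log2 abundance with Benjamini-Hochberg FDR),
    positional classification of lncRNAs into five classes with cis-target
    search, a small-RNA clean-tag filter cascade with miRNA quantification,
    a rule-based plant miRNA target-prediction engine with G-U wobble
    scoring and a duplex energy-ratio test, weighted co-expression module
    detection (soft-threshold adjacency, unsigned topological overlap,
    eigengenes, module-trait association), correlation-constrained ceRNA
    triplet assembly with network export, hypergeometric term enrichment,
    and a synthetic-data generator that plants differential expression,
    co-expression modules, anticorrelated miRNA-target pairs and ceRNA
    triplets with a machine-readable truth table so that every stage is
    testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
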