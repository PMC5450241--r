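Package: pupdevo
Title: Comparative Developmental Transcriptomics of Trophic Specialists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for comparative developmental
    transcriptomics across closely related taxa, modelled on studies of
    craniofacial divergence in San Salvador Island pupfishes. Provides
    expression filtering and trimmed-mean-of-M-values (TMM)
    normalization, negative-binomial likelihood-ratio tests for pairwise
    differential expression per developmental stage, focal-taxon
    intersection-set discovery with constitutive-expression
    classification, permutation and hypergeometric tests for curated
    gene-list overrepresentation, pre-ranked gene set enrichment
    analysis (GSEA) with the classic scoring scheme, per-stage principal
    component ordination with loading-based gene rankings, and
    coverage-filtered interval extraction for building a phylogenomic
    supermatrix. A negative-binomial simulator with planted
    differential-expression truth generates complete synthetic
    experiments for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    cluster,
    withr
Config/testthat/edition: 3
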