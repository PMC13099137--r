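Package: comap
Title: Single-Cell Chromatin and Transcriptome Co-Mapping Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for paired single-cell histone-modification
    (ChIC) and full-length transcriptome data during early development.
    Implements TF-IDF/LSA embedding of sparse chromatin bin counts with
    pivoted unique normalization, metacell aggregation with per-mark
    balancing, HMM-based calling of broad H3K27me3 domains with subpeak
    refinement, regression models for cis-spreading of repressive chromatin
    and polycomb gene silencing, chromatin-transcription coupling per
    metacell, negative-binomial differential chromatin analysis over
    metacell pseudo-replicates, and lasso-based classification of
    transcription factors as activators or repressors. Ships a synthetic
    paired-modality data generator with planted ground truth so every stage
    has a recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo: Rcpp
Imports:
    Rcpp,
    Matrix,
    data.table,
    glmnet,
    MASS,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite,
    withr
Config/testthat/edition: 3
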