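Package: tfdge
Title: Differential Transcription Factor Binding Models of Differential Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative modelling of gene expression between two cell types
    from multi-factor ChIP-Seq binding data. Builds a merged peak-coverage
    atlas across transcription factor (TF) ChIP-Seq samples, assigns peak
    regions to genes by promoter/intragenic/nearest-gene rules, computes
    differential binding (delta-TF) and differential expression (delta-GE)
    scores, and fits cross-validated multiple linear regression and
    generalised additive models (with pairwise TF interaction smooths,
    REML-selected penalties) that predict delta-GE from delta-TF. Also
    provides region partitioning into cell-type-specific and common peaks,
    motif-content matrices from position-weight-matrix scanning of central
    peak windows, TF co-occupancy statistics, residual-based association
    tests, and a fully deterministic synthetic-data generator with recorded
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    mgcv,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
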