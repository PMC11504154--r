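Package: mpdicho
Title: Migration-Proliferation Dichotomy Analysis for Tumour Expression Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tests the migration-proliferation dichotomy in bulk tumour
    transcriptomes. Computes geometric-mean proliferation and migration
    signature indices from gene expression matrices, the per-sample
    Dichotomy Index (DI), stage-stratified Pearson correlations with
    Fisher z confidence intervals, dominance-shift tests, a lightweight
    phenotype-permutation gene set enrichment engine with leading-edge
    extraction and core-gene overlap z statistics, and a model
    discrimination verdict (dichotomy vs. simultaneous vs.
    phenotype-refractory). Includes a latent-factor synthetic cohort
    generator, readers and writers for GCT 1.2, GMT, CLS and clinical
    tables, and an end-to-end analysis pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
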