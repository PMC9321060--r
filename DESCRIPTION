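Package: lymphomap
Title: Self-Organizing Map Portrayal and Spot-Module Classifiers for
    Lymphoma Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Whole-transcriptome self-organizing map (SOM) portrayal for
    germinal-center-derived B-cell lymphoma cohorts: metagene landscapes and
    per-sample expression portraits, segmentation of over-expression spot
    modules as candidate classifier gene sets, per-sample gene-set Z-score
    (GSZ) signature scoring, signature-to-spot Fisher enrichment, ROC/AUC
    benchmarking of spot and literature classifiers with random-subset
    resampling stability, combinatorial pattern-type (PAT) stratification,
    and an optional fully connected neural-network portrait classifier.
    Includes a synthetic-cohort generator that plants spot-like co-expression
    modules with subtype-specific activation and a continuum between subtypes,
    so every stage of the pipeline is testable without access to a cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    limma,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
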