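Package: hdpm
Title: Heart-Disease Prediction with Hybrid Feature Selection, Cluster-Based
    Resampling and Metaheuristic-Trained Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end clinical risk-prediction pipeline for tabular
    heart-disease records in the UCI 14-attribute dialect. Provides cohort-based
    imputation and standard scaling, heart-rate-variability and signal feature
    extraction, hybrid genetic-algorithm plus recursive-feature-elimination
    feature selection, a cluster-aware under/over-sampling resampler that
    balances training data with SMOTE while keeping validation and test sets
    untouched, a multilayer neural network with Gaussian hidden activations
    trained by backpropagation, an adaptive elephant-herd metaheuristic for
    network-weight optimization, stratified k-fold evaluation with standard
    confusion-matrix metrics, and a seeded synthetic-data generator so that
    every stage is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    caret
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
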