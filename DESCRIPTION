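Package: toxbalance
Title: Imbalance-Aware Toxicity Endpoint Classification with Rough-Set
    Feature Selection and Iterative Hybrid Resampling
Version: 0.1.0
Authors@R:
    person("toxbalance", "maintainers", email = "toxbalance@example.org",
           role = c("aut", "cre"))
Description: Tools for binary toxicity-endpoint classification on molecular
    descriptor tables with heavily imbalanced classes. Provides rough-set
    attribute reduction (quick reduct, entropy-based, and discernibility-matrix
    strategies over discretized decision tables), class-rebalancing methods
    (random under- and over-sampling, SMOTE interpolation, and an iterative
    hybrid sampler that removes borderline "Danger" majority samples and
    replicates safe minority samples before Tomek-link cleaning), a seeded
    bagging ensemble over a built-in decision-tree weak learner, and
    imbalance-aware evaluation (sensitivity, specificity, geometric mean,
    ROC/AUC, class-scatter diagnostics) with a leakage-free stratified
    cross-validation harness. Includes a synthetic-data generator for
    imbalanced two-class descriptor tables with controllable separation,
    overlap and label noise, and a command-line interface for the full
    selection-resampling-classification pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
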