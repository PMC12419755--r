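Package: rrscreen
Title: Window-Based Screening for Psychotic Disorders from R-R Interval Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies short rolling windows of beat-to-beat (R-R) interval
    recordings and aggregates the window decisions into a single
    schizophrenia/bipolar-versus-control call per person. Implements
    person-confined 5-fold and leave-one-out cross-validation, six window
    classifiers (1-nearest neighbor, multilayer perceptron, RBF support vector
    machine with hypothesis-test feature selection, a bagged ensemble of
    support vector machines, gradient-boosted trees, and a GRU plus fully
    convolutional network hybrid), learned person-level decision thresholds,
    classifier-comparison statistics (Friedman, pairwise Wilcoxon signed-rank
    with Benjamini-Hochberg correction, paired Cohen's d), and an explanation
    layer with exact Shapley attributions for tree ensembles and lag-structured
    autocorrelation summaries. A synthetic autoregressive R-R cohort generator
    provides data with the documented group structure so that the whole
    pipeline is testable without any recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    xgboost,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
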