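Package: dpnet
Title: Differentially Private Deep Representation Learning for Omics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Trains (alpha, epsilon)-Renyi differentially private neural
    networks for privacy-sensitive molecular data. Provides a Renyi
    differential privacy accountant for the Gaussian mechanism with additive
    composition, differentially private stochastic gradient descent with
    per-example l2 gradient clipping, denoising autoencoders for
    expression-like and copy-number matrices, transfer-learned private binary
    classifiers and per-drug sensitivity regressors, an Indicator-driven
    hyperparameter search, evaluation utilities (accuracy, ROC AUC, Spearman
    rank correlation, stratified cross-validation), a seeded synthetic-data
    generator, and publishable model bundles that contain parameters only.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
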