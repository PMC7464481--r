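Package: omixnet
Title: Multi-Omics Late-Integration Neural Networks for Cancer Subtype
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies cancer molecular subtypes from aligned multi-omics
    profiles (mRNA expression, gene-level DNA methylation, gene-level copy
    number) with a late-integration feedforward neural network: one encoding
    subnetwork per omics type (fully connected layer, batch normalization,
    ReLU, dropout), concatenation of the learned representations with L2
    normalization, and a jointly trained classification head (sigmoid /
    binary cross-entropy for pairwise tasks, softmax / cross-entropy for
    multiclass). Includes chi-squared (class-sum) feature ranking with top-k
    selection, reciprocal-class-count weighted mini-batch sampling for
    imbalanced cohorts, balanced-accuracy / AUC evaluation with stratified
    k-fold cross-validation, a leave-one-subtype-out ablation harness, IHC
    marker based breast-cancer subtype labelling, and a seeded synthetic
    three-omics data generator with planted class signal for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
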