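Package: dompath
Title: Meta-Path Topological Features for Protein Domain-Disease
    Association Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds a global heterogeneous information network from
    structural domain-protein, protein-protein, protein-disease,
    disease-disease similarity and domain-disease edge lists, extracts
    meta-path topological features (path counts from sparse commuting
    matrices and their random-walk row normalization), and trains
    gradient-boosted tree classifiers (with random forest, support vector
    machine and naive Bayes baselines) to predict candidate associations
    between protein structural domains and diseases.  Includes a seedable
    synthetic network generator with planted domain-disease signal,
    leakage-controlled train/test construction, grid-search
    cross-validation, ROC/AUC and F1 evaluation, and a command-line
    interface for end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    xgboost,
    randomForest,
    e1071,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC,
    withr
Config/testthat/edition: 3
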