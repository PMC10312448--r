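Package: morphoblend
Title: Blending Ensembles for Landmark-Based Shape Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A streamlined workflow for classifying high-dimensional
    landmark-based shape phenotypes. Provides generalized Procrustes
    superimposition and Procrustes distances, anomaly filtering by the
    Procrustes-distance interquartile fence, stratified three-way data
    partitioning, principal component feature extraction fitted on training
    data only, a family-spanning registry of base classifiers tuned by
    random discrete hyperparameter search under bootstrap resampling,
    blending ensembles that stack top-ranked learners' held-out validation
    predictions under a generalized linear model or random forest
    metalearner, weighted ensemble variable importance, a full
    classification-metric suite, dataset-level phenotypic property
    statistics with meta-regressions, a synthetic landmark-data generator,
    and TPS/CSV readers and writers with a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    nnet,
    rpart,
    randomForest,
    e1071,
    glmnet,
    ipred,
    caret,
    mixOmics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
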