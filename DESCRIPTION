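Package: ptmlyield
Title: Perturbation-Theory Machine Learning Models of Cross-Coupling
    Reaction Yields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds perturbation-theory machine-learning (PTML) models of
    reaction yield for recyclable nanoparticle-catalyzed cross-coupling
    reactions. Reaction trials are featurized as deviations of molecular
    descriptors and reaction-condition variables from moving averages taken
    within condition partitions, anchored to a reuse-cycle reference yield.
    Provides the data model and readers for flat reaction tables and the
    SURF exchange format, group-mean imputation of missing catalyst amounts,
    the four standard condition-partition schemes, forward-stepwise and
    expert-guided multiple linear regression with leave-one-out and
    leave-group-out cross-validation, built-in evaluators for the published
    fitted equations, shallow neural counterparts (linear network,
    multilayer perceptron, radial basis function, generalized regression
    network) for regression and binary yield classification, an evaluation
    suite (stratified every-fourth split, yield binarization, regression
    and classification metrics, ROC/AUC, permutation feature importance),
    and a synthetic-data generator with planted models for end-to-end
    testing and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
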