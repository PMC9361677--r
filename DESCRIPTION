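Package: dtibalance
Title: Drug-Target Interaction Prediction with One-Class-SVM Reliable
    Negative Selection
Version: 0.1.0
Authors@R:
    person("DTI", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A chemogenomic pipeline for drug-target interaction (DTI)
    prediction under positive-unlabeled learning. Computes drug descriptors
    (1024-bit Morgan/ECFP4 fingerprints, 30 constitutional descriptors) and
    protein descriptors (amino-acid composition, dipeptide composition),
    assembles the four drug-protein pair feature sets plus their union,
    selects reliable negative pairs from the unlabeled pair grid with a
    one-class support vector machine consensus over feature sets, provides
    random-undersampling and SMOTE class-balancing baselines, benchmarks
    five classifiers (RBF-SVM, random forest, SAMME AdaBoost, and
    depth-wise/leaf-wise second-order gradient boosting) under stratified
    10-fold cross-validation, and reports accuracy, precision, recall, F1,
    MCC, MSE and ROC AUC. A synthetic-data generator with hidden truth
    labels makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
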