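Package: forgenet
Title: Forest Graph-Embedded Feature Selection with SVM Classification
    for Compound Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies bioactive compounds from fused molecular
    fingerprints (ECFP6, MACCS keys and a fixed block of 2D
    physicochemical descriptors). A random forest fitted on the fused
    features is converted into a feature graph by taking the union of
    parent-child split-feature edges over all trees; the graph masks the
    first layer of a deep feed-forward network whose trained weights
    yield Graph Connection Weights (GCW) importance scores. The
    top-ranked features feed a kernel support vector machine trained by
    a dual (SMO-style) solver. Includes a planted-feature synthetic data
    generator, stratified cross-validation, confusion-matrix metrics and
    ROC/AUC evaluation for decoy-based virtual-screening studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    ranger,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
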