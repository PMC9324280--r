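Package: bbrent
Title: Stable Radiomic Feature Selection with Bagged-Boosted Repeated
    Elastic Nets
Version: 0.1.0
Authors@R:
    person("BB-RENT", "Maintainers", email = "bbrent@example.org",
           role = c("aut", "cre"))
Description: A pipeline for discriminating two classes from tabular
    radiomic feature data with an emphasis on the stability of the
    feature-selection step.  Provides preliminary feature filtering
    (variance, intraclass-correlation agreement between repeated
    delineations, univariate association), the bagged-boosted repeated
    elastic net (BB-RENT) ensemble feature selector together with its
    single elastic net, RENT, boosted-RENT and bagged-RENT comparators,
    selection-stability metrics (mean pairwise Jaccard index and the
    Nogueira stability score with its asymptotic significance test), a
    classifier stage (linear support vector regression, logistic
    regression, random forest, perceptron, k-nearest neighbours) with
    stratified cross-validation, Youden-index thresholds and bootstrap
    confidence intervals, a reciprocal-weighted fold-model ensemble with
    a unit decision threshold, and a synthetic feature-table generator
    used to exercise the whole pipeline end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    FNN,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
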