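Package: riskrank
Title: Ranking Risk Factors for Binary Outcomes with Machine Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for descriptive epidemiology that replace single
    multivariable "kitchen-sink" regressions with a model-agnostic
    ranking of predictors.  Fits penalized logistic regressions (LASSO,
    elastic net), random forests and single-hidden-layer neural networks
    under a nested cross-validation tuning scheme optimised for AUC,
    ranks predictors with permutation and partial-dependence-based
    (FIRM) variable importance, attaches bootstrap percentile confidence
    intervals to the importance scores, computes one- and two-dimensional
    partial dependence, and measures two-way interaction strength from
    the partial-dependence surface.  A synthetic survey-data generator
    with planted linear, curvilinear and sign-flip interaction effects
    supports end-to-end testing without access to any real survey.
License: MIT
Encoding: UTF-8
Imports:
    glmnet,
    jsonlite,
    nnet,
    ranger,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
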