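Package: th2score
Title: Composite Th2-Inflammation Scoring and Diagnostic Accuracy Analysis
Version: 0.1.0
Authors@R:
    person("th2score", "Maintainers", email = "maintainers@th2score.org",
           role = c("aut", "cre"))
Description: Tools for building and evaluating a composite 0-4 diagnostic
    score from four T-helper-2 inflammation biomarkers (blood eosinophil
    count, total serum IgE, fractional exhaled nitric oxide, and skin prick
    positivity) in asthma screening cohorts. Provides cohort CSV input and
    validation, biomarker dichotomization at predefined clinical cutoffs,
    2x2 diagnostic-accuracy metrics with Wilson or Clopper-Pearson
    confidence intervals, exact Fisher and Pearson chi-square contingency
    tests, empirical ROC curves with trapezoid and Mann-Whitney AUC and
    DeLong confidence intervals, Youden-index optimal cutoff selection,
    two-group comparisons (t, exact/approximate Mann-Whitney) with
    automatic test selection, binomial logistic regression fitted by
    iteratively reweighted least squares with Wald inference and
    Nagelkerke R-squared, and a seeded synthetic-cohort generator with
    log-normal biomarker marginals fitted to published median/IQR
    summaries via a Gaussian copula.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
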