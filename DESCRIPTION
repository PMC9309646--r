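Package: ordinet
Title: Regularized Partial-Correlation Networks for Ordinal Symptom Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and stability analysis of Gaussian graphical models for
    Likert-type questionnaire data. Computes Spearman correlation input,
    EBIC-selected graphical-LASSO partial-correlation networks, expected
    influence and bridge expected influence centrality with percentile-based
    node selection, nonparametric bootstrap edge confidence intervals and
    difference tests, and case-dropping correlation-stability (CS)
    coefficients. Includes a latent-Gaussian ordinal data simulator with a
    known ground-truth network for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp,
    igraph,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
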