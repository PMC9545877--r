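Package: symptomnet
Title: Symptom Network Analysis for Ordinal Questionnaire Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimation and analysis of psychometric symptom networks from
    item-level ordinal questionnaire data. Implements unregularized Gaussian
    graphical model estimation (graphical-lasso regularization path, constrained
    maximum-likelihood refits and stepwise BIC edge search), signed-network
    centrality indices (expected influence, closeness, betweenness), bridge
    expected influence across construct clusters, weighted clique-percolation
    community detection with intensity thresholding, nonparametric bootstrap
    edge stability and case-dropping centrality stability analysis, and a
    latent-Gaussian ordinal data generator calibrated to published summary
    statistics of a loneliness-depression-anxiety network study.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    igraph,
    jsonlite,
    mvtnorm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
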