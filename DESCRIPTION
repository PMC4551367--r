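Package: grangernet
Title: Prior-Knowledge-Driven Granger Causality Inference of Gene Regulatory Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers directed gene regulatory networks from short time-series
    expression data by Granger causality modeling. Implements pairwise
    (bivariate) Granger causality with F-tests, ridge/lasso/elastic-net
    regularized vector-autoregressive (VAR) models for the n >> T regime, and
    a two-step prior-knowledge ridge method (CGC-2SPR) that pulls the VAR
    coefficient matrix toward a sign-adjusted prior weight matrix built from a
    pairwise gene association graph. Includes a Monte Carlo permutation
    estimator of edge significance for settings where F-tests are invalid,
    mutual-information network baselines (ARACNE, MRNET and time-delayed
    variants), a modularized hierarchical network and expression simulator
    with a clique prior generator, and precision-recall / F1 evaluation
    against golden-standard edge lists.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    parallel,
    withr,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
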