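Package: ekdesign
Title: Empirical-Kriging Optimal Design for Gaussian Random Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for computing monitoring designs for Gaussian random
    fields under the empirical-kriging (EK) criterion, the maximum over a
    prediction region of the kriging variance corrected to first order for
    the uncertainty of plug-in covariance-parameter estimates. Provides the
    corrected prediction variance, Fisher-information surrogates for the
    trend and covariance-parameter blocks, the compound D-optimality
    criterion combining them, non-dominated (Pareto) filtering and upper
    convex hulls in the two-criterion plane, and two search algorithms that
    restrict expensive EK evaluations to the Pareto front: simulated
    annealing over the compound criterion with rook-clique local search, and
    a simplified exchange algorithm. Includes exponential and Matern
    correlation kernels with geometric anisotropy, universal-kriging
    predictor weights, exhaustive maximin/minimax Latin hypercube
    construction, a seeded field simulator, and evaluation studies on
    simulated fields.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
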