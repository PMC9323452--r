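Package: vitalcorr
Title: Temporal Correlations Among Demographic Parameters from
    Capture-Recapture Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and hierarchical Bayesian estimation of temporal
    correlations among vital rates (juvenile survival, adult survival,
    reproductive probability, reproductive success, productivity) from
    individual-based capture-recapture data with imperfect detection.
    Provides a generative simulator for correlated vital-rate histories,
    a hidden Markov forward likelihood over latent alive/breeding states,
    an adaptive Metropolis-within-Gibbs sampler with a parameter-expanded
    Cholesky prior on the temporal variance-covariance matrix,
    cross-species synthesis of posterior correlations (grand means, sign
    probabilities, correlation-type contrasts), and elasticity-based
    generation time from age-structured projection matrices together with
    a pace-of-life meta-regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    coda,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
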