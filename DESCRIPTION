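Package: perceptlearn
Title: Trial-by-Trial Hierarchical Bayesian Models of Perceptual Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling trial-level accuracy in perceptual learning
    experiments. Accuracy is described by a chance-floored Weibull (Quick)
    psychometric function whose threshold decays as an exponentially
    saturating function of trial number; the components of change (starting
    threshold, asymptotic threshold, and rate) carry group fixed effects --
    including monotonic ordinal effects -- and by-participant random effects.
    Estimation is by Hamiltonian Monte Carlo over an analytically
    differentiated log posterior; models are compared with bridge-sampling
    marginal likelihoods reported as base-3 log Bayes factors. Includes a
    synthetic-data generator emulating a texture oddball detection design,
    exact-binomial at-chance participant screening, and an end-to-end
    pipeline with run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
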