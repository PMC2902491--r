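Package: snhurdle
Title: Two-Part Skew-Normal Hurdle Models for Zero-Inflated Repeated
    Measures
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits random-effects two-part (hurdle) mixture models for
    semicontinuous longitudinal outcomes: a probit or logit model for the
    probability of a positive response coupled with a log-skew-normal
    model (Sahu-Dey-Branco parameterization) for the magnitude of
    positive responses, with correlated bivariate-normal subject-level
    random intercepts. Estimation is by maximum marginal likelihood over
    a Gauss-Hermite product rule, either centred at the random-effects
    prior or adaptively recentred per subject at the posterior mode.
    Includes Wald tests, a likelihood-ratio test for the skewness
    parameter, AIC/BIC, a probit/log-beta simulation framework for
    robustness studies of the severity distribution, and utilities for
    aggregating daily respiratory symptom diaries into weekly average
    scores.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    pracma,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
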