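Package: ciermix
Title: Mixture IRT and Continuous-Time Latent Markov Modelling of Careless
    Responding in Intensive Longitudinal Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Separates attentive from careless/insufficient-effort (C/IER)
    responding in intensive longitudinal Likert data (e.g., ecological
    momentary assessment). Combines a confirmatory two-component mixture of
    graded response models (an attentive GRM and a constrained
    category-preference GRM for inattentive responses) estimated by marginal
    maximum likelihood with a three-step continuous-time latent Markov model
    for state transitions: modal state assignment with classification-error
    correction, covariate-dependent transition intensities via matrix
    exponentials, Wald tests and backward covariate selection. Includes a
    synthetic-data generator for planted C/IER patterns (uniform random,
    midpoint preference, straightlining, category-preference GRM), loading
    decay and two-factor measurement violations, and a simulation-study
    harness computing bias, sensitivity and specificity of C/IER detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
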