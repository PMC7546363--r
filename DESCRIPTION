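Package: gazehmm
Title: Bayesian Hidden Markov Modelling of Gaze Scanpaths with Group Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Learns data-driven regions of interest (ROIs) from eye-tracking
    scanpaths with variational Bayesian Gaussian hidden Markov models over
    fixation position and duration, selects the number of hidden states by
    the evidence lower bound, derives category-level transition and fixation
    variables (face/body/non-social), and compares clinical groups with
    linear mixed-effects models. Includes dispersion-based fixation
    detection with recording quality control, a hierarchical reduction of
    individual models to a representative model, and a synthetic-cohort
    generator with planted group effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    lme4,
    mclust,
    lmerTest,
    emmeans,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
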