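Package: rotabayes
Title: Hierarchical Bayesian Analysis of Crop-Rotation Effects on Cotton
    Yield and Lygus Pressure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing field-year crop records from commercial
    cotton production: hierarchical Bayesian linear mixed models with
    crossed field and year random effects fit by conjugate Gibbs sampling,
    posterior contrast summaries (highest-posterior-density intervals and
    sign probabilities), a two-stage meta-regression linking prior-crop
    effects on Lygus hesperus densities to effects on lint yield, and a
    synthetic-data generator with known ground truth for calibration and
    parameter-recovery studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    readr,
    rlang,
    tibble,
    ggplot2,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    optparse
Config/testthat/edition: 3
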