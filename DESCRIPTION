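Package: cgrfs
Title: Nonparametric Estimation of Chronic GvHD- and Relapse-Free Survival
    in Non-Markov Multistate Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of chronic graft-versus-host disease (GvHD-) and
    relapse-free survival after hematopoietic stem cell transplantation,
    a composite endpoint with chronic GvHD as a recurrent event.  Implements
    the Aalen-Johansen estimator in a progressive six-state model and in an
    illness-death model with recovery, and a linear combination of five
    Kaplan-Meier estimators in the progressive model.  Provides a wild
    bootstrap for the Kaplan-Meier combination based on multiplier resampling
    of the Nelson-Aalen martingale increments and a functional delta method
    transform, Efron's bootstrap by resampling individuals, log-log
    transformed pointwise confidence intervals and simultaneous confidence
    bands, and a gamma-frailty simulator for coverage experiments in
    deliberately non-Markov scenarios.
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
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
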