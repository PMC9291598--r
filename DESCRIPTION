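Package: aipwcif
Title: Doubly Robust Regression on Cumulative Incidence Functions with
    Interval-Censored Competing Risks and Missing Event Types
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semiparametric regression on cumulative incidence functions for
    interval-censored competing-risks data when some event types are missing
    at random. Implements an augmented inverse-probability-weighted (AIPW)
    sieve maximum-likelihood estimator with monotone B-spline baselines under
    the generalized odds rate transformation family, two-stage logistic
    nuisance models with auxiliary covariates, nonparametric and stratified
    bootstrap variance estimation, complete-case and multiple-imputation
    comparators with Rubin's rules, a fully specified synthetic-data
    generator (proportional-odds Gompertz subdistributions, exponential
    visit process, logistic missingness), and a Monte Carlo study pipeline
    reporting percent bias, Monte Carlo standard deviation, average standard
    error, and empirical coverage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    nnet,
    parallel,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
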