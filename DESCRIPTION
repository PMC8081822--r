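Package: hfamc
Title: Monte Carlo Inference for the Home-Field Advantage in Closed-Door
    Soccer Matches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tests whether changes in home-team performance observed in
    soccer matches played behind closed doors are meaningful or explainable
    by sampling variability. Implements seven home-team share statistics
    (points, goals, shots, possession, fouls, yellow cards, red cards), a
    Monte Carlo null built by repeatedly subsampling baseline seasons
    without replacement at the closed-door sample size, one-sided empirical
    tail p-values with configurable tie handling, an exact enumeration
    oracle for small instances, percentile-bootstrap confidence intervals
    for baseline shares, and a seeded synthetic league generator so the
    whole inference chain is testable without access to historical match
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    optparse,
    readr,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
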