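Package: banditfit
Title: Reinforcement-Learning Models with Probability Weighting for
    Two-Option Reward Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a 60-trial two-option probabilistic reward task
    (0.75/0.25 contingency re-randomized across blocks, complementary reward
    magnitudes), implements eight reinforcement-learning models -- static and
    Pearce-Hall dynamic learning rules, with and without a linear probability
    weighting parameter -- as forward agents and likelihood evaluators, fits
    them per subject by maximum a posteriori estimation with multi-start
    Nelder-Mead search and Laplace-approximation model evidence, and provides
    the downstream group analyses: proportion-correct scoring, sex-by-stress
    factorial contrasts, covariate-adjusted sex-difference models, and
    parameter-performance regressions. A synthetic cohort generator with a
    sex-by-stress group structure makes the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
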