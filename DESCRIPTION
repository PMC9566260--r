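Package: ammsim
Title: Agent-Based Simulation of Adaptive Motivation and Wellbeing Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates populations of agents that learn to respond to
    fitness-relevant situations through prediction-error-driven reinforcement
    learning and niche-construction effort allocation, and that evolve over
    generations under truncation selection on heritable instincts and cue
    values. Provides a reflective-wellbeing statistic (the positively valued
    share of weighted prediction errors), population summaries of the evolved
    negativity bias in prediction errors, and a hedonic-adaptation shock
    experiment in which the frequency of a single situation is transiently
    multiplied while reinforcement and effort learning are frozen. Results are
    returned as tibbles with broom-style tidy() and glance() methods and
    ggplot2 autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
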