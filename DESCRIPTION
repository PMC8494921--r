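Package: cultsel
Title: Agent-Based Simulation of Payoff-Biased Cultural Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Agent-based model of Darwinian cultural evolution in which
    agents hold discrete cultural variants drawn from a fixed payoff pool
    and update them by payoff-biased (roulette-wheel) selection among their
    own, a model's, and a freshly innovated variant, falling back on an
    uncritical default strategy (copy, innovate, or maintain) when not
    critical. Supports unstructured populations and ring-structured
    populations with Gaussian neighbourhoods, records Gini-Simpson
    diversity and mean variant payoff trajectories, and provides a
    deterministic parameter-sweep harness with replicate aggregation,
    tidy CSV/JSON output, and trajectory plots.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    ggplot2,
    readr,
    rlang,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
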