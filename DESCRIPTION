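Package: culturesim
Title: Spatially Explicit Agent-Based Simulation of Cumulative Adaptive Culture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A spatially explicit agent-based model of the evolution of
    cumulative adaptive culture under resource-driven natural selection.
    Individuals forage on a grid of renewable resources, learn subsistence
    traits from parents, group members and (optionally) neighbouring groups,
    improve trait skill through copying error, and invent new traits when
    experienced and under resource pressure; groups grow, fission and migrate
    under an explicit energy budget. The package provides a fast compiled
    simulation engine, reproducible multi-replicate experiment sweeps over
    resource availability, selection differential, interaction regime and
    innovation/learning costs, and end-value statistics (exact Wilcoxon
    rank-sum tests with Bonferroni correction, replicate summary tables) for
    comparing parameter cells.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
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
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
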