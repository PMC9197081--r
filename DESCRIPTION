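Package: memdyn
Title: Learning and Evolution of Strategy Spaces in Repeated Games
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying direct reciprocity between players that are
    restricted to strategy spaces of different memory capacity (unconditional,
    reactive, memory-1 and memory-2 strategies) in infinitely repeated two by
    two games. Provides exact payoff computation through the Markov chain over
    round outcomes (stationary-distribution and Press-Dyson determinant
    routes), introspection-dynamics learning between two players with a Fermi
    acceptance rule, space-versus-space tournaments with wins, score, self
    payoff and combined-score measures, and replicator dynamics of the
    resulting supergame between strategy spaces, including detection of
    memory dilemmas. Includes a compiled simulation core for long learning
    runs, tidy result tables and plotting helpers, and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    deSolve,
    tibble,
    dplyr,
    tidyr,
    purrr,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
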