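Package: pcdbet
Title: Stochastic Models of Programmed Cell Death as an Accessory to
    Microbial Bet Hedging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and closed-form analysis of competitions between a
    genotype that performs programmed cell death (PCD+) and one that does
    not (PCD-), in environments with recurring disasters that annihilate
    one of two interconvertible phenotypes.  Provides the deterministic
    per-round map and its cost/benefit theory (cost decay factor,
    exclusive-diversification probability, optimal stochastic switch rate,
    extinction risk, benefit-to-cost ratio), a spatially-implicit
    stochastic competition model with a fixed assortment parameter, a
    spatially-explicit 2D lattice model in which assortment is emergent
    and locally measured, and a 3D patch-structured agent-based model with
    reproduction, migration and disaster bottlenecks.  Includes parameter
    sweep drivers, broom-style tidiers, ggplot2 autoplot methods and a
    reproducible experiment runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
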