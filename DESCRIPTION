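Package: mtswarm
Title: Agent-Based Simulation of Microtubule Substructure Self-Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A swarm-engineering simulator of microtubule substructure
    self-organization in a bounded two-dimensional tray. Alpha and beta
    tubulin agents under impulsive random forcing form heterodimers, are
    activated by discrete GTP particles, and polymerize into protofilaments
    or twelve-member rings; extended rules add length-dependent terminal
    breakage with GDP-to-GTP nucleotide recycling. Includes per-iteration
    analytics (population counts, chain statistics, moving-average GTP
    consumption rate), presets for the reference experiments, replicate
    management, tidy accessors and ggplot2 visualisations, plus a small
    command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    optparse,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
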