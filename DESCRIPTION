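Package: mesosync
Title: Cluster Synchronisation in Spatially Embedded Delayed Kuramoto Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of delayed, noisy Kuramoto oscillator
    networks embedded on toroidal hexagonal lattices, as a mesoscale model of
    neocortical dynamics. Generates distance-constrained random directed
    networks whose wiring probability decays as a power of inter-node
    distance, integrates the delayed phase equations with an Euler solver,
    and quantifies synchrony, metastability, sliding-window functional
    interactions, temporal community structure with module tracking,
    participation coefficients, and module-level mean-field dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    igraph,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    generics,
    ggplot2,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    patchwork
Config/testthat/edition: 3
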