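Package: epicompete
Title: Multi-Scale Cellular Potts Simulation of Epithelial Cell Competition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of cell competition in epithelial
    monolayers. A two-dimensional cellular Potts model with Metropolis
    dynamics resolves cell shape, adhesion, elasticity and motility, and a
    per-frame cell automaton applies probabilistic rules for growth under
    contact inhibition, adder-based division, density-dependent
    (mechanical) apoptosis, contact-dependent (biochemical) apoptosis and
    live extrusion. Includes the measurement layer used to analyse such
    simulations (neighbour graphs, local density, heterotypic contact,
    mixing entropy, event probabilities, mean squared displacement,
    population summaries), scenario drivers for pure-population growth,
    stretch-release homeostasis, mixed-population competitions and
    parameter sweeps, plus trajectory/snapshot input and output and a
    command-line interface.
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
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
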