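Package: cpresim
Title: Agent-Based Simulation and Resilience Analysis of a Common-Pool
    Resource System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A discrete-time stochastic agent-based model of consumers
    harvesting a renewable, diffusing resource on a square lattice, with
    optional heritable (mutated) decision parameters so that the agent
    population can adapt through natural selection. Around the simulator the
    package provides the analysis layer needed to quantify adaptation and
    resilience: replicate ensembles and time-dependent or time-averaged
    histograms of the population size, earth-mover's (1-D optimal transport),
    Euclidean and Jensen-Shannon distances between output distributions,
    adaptation-effect and adaptation-rate curves, stationarity and ergodicity
    tests for stochastic simulator output, exponential extinction-rate fits to
    survival curves, harvest-cost sweeps, pressure-ramp experiments and
    adaptation-rate versus pressure phase diagrams.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
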