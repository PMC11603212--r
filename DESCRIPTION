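Package: trapshy
Title: Trap-Shyness Inference and Lure-Strategy Simulation for Invasive
    Predator Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Stochastic, spatially explicit individual-based simulation of an
    invasive predator population (brushtail possum) under kill-trapping with
    heterogeneous trap-shyness. Individual nightly capture probabilities
    combine a half-normal encounter model around the home-range centre with a
    Beta-distributed per-individual probability of interacting with a lured
    device. The trap-shyness distribution and the initial population size are
    calibrated from a capture time series by rejection approximate Bayesian
    computation, and the calibrated model simulates multi-lure control
    scenarios (simultaneous lure combinations and catch-rate-triggered lure
    switches) to compare eradication strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
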