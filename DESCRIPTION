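Package: phasereplay
Title: Associative Memory for Phase-Coded Spike Patterns in Integrate-and-Fire Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stores phase-coded periodic spike patterns in a recurrent leaky
    integrate-and-fire (spike-response) network through a spike-timing-dependent
    plasticity (STDP) learning window, and provides the simulation and analysis
    machinery to cue, replay and score the stored memories: an overlap order
    parameter between replayed and stored phase patterns, period and replay
    frequency estimation, regime classification (retrieval, spurious, silent),
    storage-capacity and persistence sweeps, and robustness experiments with
    Poissonian input noise and heterogeneous spiking thresholds. Simulation and
    weight-construction inner loops are implemented in C++ via Rcpp; results are
    returned as tidy tibbles with ggplot2 plotting helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
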