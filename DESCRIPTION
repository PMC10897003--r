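Package: alnsim
Title: Whole-Brain Mean-Field Network Modelling of Resting-State Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Delay-coupled whole-brain networks of adaptive exponential
    integrate-and-fire (AdEx) mean-field nodes driven by a structural
    connectome. Provides Fokker-Planck transfer-function tables for the
    exponential integrate-and-fire population, Ornstein-Uhlenbeck background
    noise, somatic adaptation, Balloon-Windkessel BOLD conversion,
    connectivity and temporal-dynamics metrics (functional connectivity,
    global brain connectivity, Kuramoto synchrony, metastability),
    group-comparison statistics (Welch t, chi-square, Hedges' g, label
    permutation tests), perturbation experiments over fixed-seed virtual
    subject cohorts, an evolutionary parameter-fitting routine, and
    synthetic generators for connectomes, functional-network partitions,
    two-group regional BOLD data and head-motion tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tibble
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
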