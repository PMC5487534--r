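Package: strpfr
Title: Hybrid Single-Cell and Population Simulation of Scale-Down
    STR-PFR Bioreactors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the transcriptional and translational response of an
    Escherichia coli chemostat population to repeated nitrogen starvation in
    a stirred-tank / plug-flow (STR-PFR) scale-down reactor.  A deterministic
    one-dimensional lattice model tracks RNA polymerases, ribosomes and
    RNases on the trp operon during one starvation-induced expression
    episode; a Gillespie stochastic simulation of PFR entry, washout and
    division events tracks every cell of the population; superposition of
    the single-cell episode over each cell's PFR-entry flags yields
    population-level mRNA and protein time courses, sampling-port profiles
    and the induction-state census.  Closed-form helpers cover growth-rate
    splitting between compartments, translations-per-mRNA quotas from
    turnover ratios, half-life conversions and steady-state protein levels
    as a function of the protein degradation constant.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
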