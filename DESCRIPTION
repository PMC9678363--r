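Package: groupsync
Title: Group Synchronization Dynamics in Ensemble Drumming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of collective sensorimotor synchronization
    in drumming ensembles. Implements classic, mean-field and hybrid
    pulse-coupled Kuramoto phase-oscillator models with onset extraction from
    zero-phase crossings, and the full timing-analysis pipeline for event
    (drum-hit onset) data: group-aggregate onset construction by kernel
    smoothing and peak picking, inter-onset-interval cleaning, detrending and
    autoregressive pre-whitening, tempo-trend and coefficient-of-variation
    performance measures, auto- and cross-correlation profiles, point-process
    transfer entropy on binned event streams, and directed-network summaries
    (causal density, mean node strength). A synthetic error-correcting tapper
    provides ground-truth data for pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    igraph,
    jsonlite,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
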