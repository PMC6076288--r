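Package: flexdecode
Title: Flexible Ensemble Decoding of Odor-Evoked Projection-Neuron Responses
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing stimulus-history effects in antennal-lobe
    projection-neuron (PN) ensembles and for decoding odor identity from
    population spike trains. Provides deterministic spike binning into 50 ms
    population response matrices, a seeded inhomogeneous-Poisson generator of
    PN ensembles with history-dependent cross-talk (suppression of shared
    responders, enhancement of previously inhibited ones), binary
    responder/latency barcodes and their set algebra, PCA/LDA population
    trajectories with contrast-enhancement statistics, a soft-margin linear
    support vector machine and a flexible m-of-n (OR-of-ANDs) template
    decoder in analog and digital forms, and an ON-OFF model that converts
    bin-wise classification probabilities into predicted palp-opening
    responses. A command-line pipeline chains simulation, characterization,
    geometry, decoding and behavioral prediction into a reproducible run.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
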