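Package: boolcpg
Title: Threshold-Logic Boolean Networks for Respiratory Rhythm Generation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Build and simulate threshold-logic Boolean networks under a
    synchronous update scheme, with exact attractor (cycle) detection.
    Provides the excitatory memory-chain bursting motifs with and without
    memory loss and self-excitation, closed-form steady-state oracles for
    both, a classifier for silent/tonic/bursting/mixed-mode spike patterns,
    and a composed three-population central pattern generator that
    reproduces 3-phase, 2-phase and 1-phase respiratory rhythms together
    with inspiration/expiration timing analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
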