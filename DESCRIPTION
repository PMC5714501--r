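Package: urophys
Title: Simultaneous Cystometry and Pontine-Cortical Electrophysiology Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing simultaneous bladder cystometry, pontine
    spike trains and cortical/pontine field potentials across micturition
    cycles: detection of voiding events from pressure traces and derivation
    of pre-, post- and intermicturition phase windows; binned and z-scored
    firing rates, peri-event rate matrices and activation-latency estimation;
    interspike-interval-criterion burst detection with per-phase summaries;
    multitaper (DPSS) power spectra, spectrograms, magnitude-squared
    coherence and repeated-measures comparison of pre-micturition epochs.
    Includes a seeded synthetic-session generator that emulates the
    statistical structure of such recordings so that every analysis stage is
    testable end to end without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
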