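Package: mutableLife
Title: Conway's Game of Life with Heritable, Mutable Rule Thresholds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A cellular-automaton model of somatic evolution built on
    Conway's Game of Life in which the three integer rule thresholds
    (death by loneliness, spontaneous birth, death by overcrowding) become
    per-site heritable genes. Newly born cells inherit the rule genome of
    a randomly chosen live Moore neighbour and, with a configurable
    mutation rate, receive an additive Gaussian perturbation of
    configurable magnitude to one randomly chosen threshold; sites reset
    to the wildtype genome (2/3/3) on death. The package provides the
    synchronous lattice update engine (C++ core), a run loop with
    steady-state detection, parameter-sweep experiment drivers
    summarising the transition from sparse Game of Life ash to dense
    tumour-like growth, readers and writers for standard Life pattern
    formats (run-length encoded and plaintext cells) and CSV grid dumps,
    and a command-line interface for reproducible headless runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
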