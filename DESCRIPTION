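Package: ramanSG
Title: Star-Graph Trace Invariants of Raman Spectra for Perturbation-Theory
    Machine Learning of Mitochondrial Oxygen Flux
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms one-dimensional Raman spectra of carbon nanotubes into
    star graphs and computes adjacency-matrix trace invariants (spectral
    moments) of the plain and recurrence-embedded adjacency matrices. Builds
    perturbation-theory machine-learning (PTML) feature tables from trace
    invariants and experimental-condition moving-average operators, and fits
    linear, neural-network and random-forest regressors for mitochondrial
    oxygen mass flux with repeated cross-validation, summary statistics and
    regression ROC (RROC) curves. Includes a synthetic-data generator for
    carbon-nanotube-like spectra and respirometry-like oxygen flux time
    series with a known generative link, so the whole pipeline can be
    exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    caret,
    graphics,
    jsonlite,
    nnet,
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
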