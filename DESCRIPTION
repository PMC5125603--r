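Package: tschmm
Title: Three-Stage Continuous Hidden Markov Models for Human Activity
    Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Hierarchical (coarse-to-fine-to-accurate) classification of
    smartphone accelerometer/gyroscope feature windows with banks of
    Gaussian-mixture continuous hidden Markov models. Includes random-forest
    variable-importance feature selection with an above-mean retention rule,
    sparse locality preserving projections (an l1 sparse-reconstruction graph
    embedding solved as a graph-Laplacian generalized eigenproblem), a classic
    k-NN/heat-kernel LPP baseline, readers and writers for the UCI-HAR
    plain-text file dialect, a synthetic data generator emulating that layout,
    confusion-matrix reporting with per-class row rates, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    ranger,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
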