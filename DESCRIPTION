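Package: emgsynergy
Title: Muscle Synergy Extraction from Surface EMG of Human Running
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extracting muscle synergies from multi-channel surface
    electromyography (EMG) recorded during treadmill running. Implements the
    full analysis chain: linear-envelope conditioning of raw EMG (zero-phase
    Butterworth filtering, rectification, amplitude normalization), gait-cycle
    time normalization to a fixed 200-point stance/swing grid, non-negative
    matrix factorization by Gaussian multiplicative updates with restarts and
    a rank sweep, model-order selection by the iterative linear-fit
    mean-squared-error criterion, classification of motor primitives into
    fundamental and combined synergies with functional phase labels, and
    gait-cycle summary statistics including the strike index. A synthetic-data
    generator produces raw-EMG-like trials, cycle-times tables and participant
    metadata with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    graphics,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
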