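Package: gridnet
Title: Grid-Cell Analysis and Continuous Attractor Network Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis suite for medial entorhinal cortex grid-cell recordings
    in open-field arenas: occupancy-normalized rate maps and spatial
    autocorrelograms, gridness scores with spike-shuffle null distributions,
    Laplacian-based firing-field segmentation with spatial specificity and
    spatial information, interspike-interval variability and bursting
    statistics, waveform-based unit typing, speed and head-direction tuning,
    pairwise spatiotemporal cross-correlation stability, and theta-band LFP
    analysis via Morlet wavelets. Includes a synthetic-data generator that
    emulates multi-session open-field experiments with known ground truth,
    and a continuous attractor network of exponential integrate-and-fire
    neurons on a periodic sheet, with perineuronal-net-removal manipulations
    (reduced excitatory-to-inhibitory coupling, increased inhibitory
    capacitance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
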