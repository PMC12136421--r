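Package: burstres
Title: Interleaved Single-Spike and Burst Resonance in a CA1 Pyramidal Neuron Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Conductance-based Hodgkin-Huxley simulation of a CA1 pyramidal
    neuron (one- or two-compartment, with persistent sodium, delayed-rectifier,
    muscarinic and A-type potassium, calcium and calcium-activated potassium
    currents and a dendritic h-current) under step and theta/gamma sinusoidal
    drive with additive white noise, plus the analysis chain for interleaved
    single-spike/burst suprathreshold resonance: spike detection, burst
    classification by a 14 ms inter-spike-interval rule, firing rate and ISI
    coefficient of variation, frequency-sweep tuning curves and resonance
    summaries, spike phase-locking statistics (PLV/PLS) in theta and gamma
    bands, quiet-interval-conditioned event probabilities, and a
    voltage-imaging event pipeline (photobleach correction, fluorescence peak
    detection, per-area interval statistics) validated on a synthetic
    fluorescence-trace generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
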