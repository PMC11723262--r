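Package: sinwfet
Title: Simulated Silicon-Nanowire FET Biosensing with Neural Signal Denoising
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end simulation and evaluation pipeline for impedimetric
    silicon-nanowire field-effect-transistor (SiNW-FET) virus biosensing.
    Generates labelled, seeded benchmark datasets of noisy/clean source-drain
    current windows from a four-element equivalent-circuit model, a Langmuir
    antigen-binding response and a structured acquisition-noise model;
    provides classical baselines (moving-average and zero-phase Butterworth
    low-pass filtering, preamplifier gain staging) and a trainable 1D
    convolutional denoising network with fixed-point inference emulation of
    an FPGA datapath; and computes the full evaluation protocol
    (clean-referenced SNR per carrier frequency, SNR improvement, noise-power
    reduction fraction, standardized MSE, and threshold-rule detection
    metrics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    arrow,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
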