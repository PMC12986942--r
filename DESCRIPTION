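Package: rezabench
Title: Exponential Band-Pass Filtering and IIR Filter Benchmarking for
    EEG and IMU Gait Signals
Version: 0.1.0
Authors@R:
    person("rezabench", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Implements the 'Reza' exponential frequency-domain band-pass
    filter with automatic edge-sharpness-driven selection of its decay
    exponent, together with classical fourth-order IIR comparators
    (Butterworth, Chebyshev Type I, elliptic) designed from analog
    prototypes in second-order-sections form, zero-phase and causal
    application, Welch power-spectral-density estimation, band-limited
    power and signal-to-noise outcome measures, one-way repeated-measures
    ANOVA with partial eta-squared and Bonferroni-corrected paired
    post-hoc tests, seeded synthetic EEG-like and IMU-gait-like signal
    generators, and an end-to-end filter benchmark pipeline with a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
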