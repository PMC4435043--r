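Package: synrates
Title: Excitatory and Inhibitory Synaptic Input Rates from a Membrane
    Voltage Trace
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers time-varying excitatory and inhibitory synaptic input
    rates from a single intracellular membrane-voltage recording.  The
    sub-threshold voltage is modelled as an Ornstein-Uhlenbeck process plus
    a nonparametric afterhyperpolarization kernel; the time-varying input
    mean and log input variance are estimated by a Gaussian assumed-density
    state-space smoother whose random-walk hyperparameters are tuned by
    expectation-maximization; the diffusion-approximation moment equations
    then convert the input statistics to total excitatory and inhibitory
    presynaptic rates.  Includes preprocessing for raw recordings (spike
    detection, spike-waveform removal, smoothing, sub-sampling, membrane
    time-constant estimation), a single-compartment conductance-based
    neuron simulator with Poisson presynaptic populations for validation,
    a particle filter/backward-simulation smoother used as an inference
    oracle, and trial-level analytics (peristimulus time histograms,
    stimulus-triggered averages, window t-tests, spike-count grouping).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
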