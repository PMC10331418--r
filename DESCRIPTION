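Package: punitbeats
Title: Beat and Mistuned-Octave Envelope Encoding in Electrosensory P-Units
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how slow beating envelopes arise when the
    quasi-sinusoidal electric organ discharge (EOD) of a wave-type electric
    fish is superimposed with a sinusoidal stimulus near integer multiples
    (mistuned octaves) of the EOD frequency, and how p-type electroreceptor
    afferents (P-units) encode them. Provides synthesis of two-tone and
    multi-harmonic EOD-like signals; competing envelope-extraction
    nonlinearities (Hilbert/analytic signal, squaring, half-wave
    rectification, exponentiated rectification) together with analytic
    predictions of the spectral peaks they generate via the pulse-train
    approximation; a stochastic adapting leaky integrate-and-fire P-unit
    model with a dendritic low-pass prefilter and a packaged table of nine
    fitted parameter sets; spike-train spectral analysis (Gaussian-kernel
    firing rates, Welch spectra, frequency and amplitude tuning curves,
    alias tracking); and jamming-avoidance-response analysis on synthetic
    frequency-shifting recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
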