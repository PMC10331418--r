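# punitbeats

Beat and mistuned-octave envelope encoding in electrosensory P-units.

## The problem

Wave-type electric fish emit a quasi-sinusoidal electric organ discharge
(EOD) at a carrier frequency f<sub>EOD</sub>. A stimulus cosine at frequency
f<sub>stim</sub> and contrast α superimposes with it,

x(t) = cos(2π f<sub>EOD</sub> t) + α cos(2π f<sub>stim</sub> t),

producing a slow beating envelope not only for f<sub>stim</sub> near
f<sub>EOD</sub> (the classical beat at Δf = f<sub>stim</sub> −
f<sub>EOD</sub>), but near *every* integer multiple of the carrier
("mistuned octaves"), at the alias frequency

f<sub>exp</sub> = |f<sub>stim</sub> − f<sub>EOD</sub> ·
round(f<sub>stim</sub>/f<sub>EOD</sub>)|,

with f<sub>EOD</sub>/2 acting as a Nyquist frequency. The raw signal's
spectrum contains only the two input frequencies, so extracting these
envelopes requires a nonlinearity. This package is for computational
neuroscientists studying that mechanism. It implements, on fully synthetic
signals:

- **Signal synthesis** — two-tone superpositions, multi-harmonic EOD-like
  carriers, SAM stimuli, per-cycle envelopes
  (`synth_superposition()`, `synth_eod()`, `synth_sam()`,
  `cycle_envelope()`).
- **Envelope nonlinearities and peak predictions** — Hilbert envelope,
  squaring, half-wave rectification ⌊x⌋₀ and its exponentiated form
  ⌊x⌋₀ᵖ, plus an analytic prediction of the spectral peaks they generate
  via the pulse-train (square-wave convolution) approximation
  (`analytic_envelope()`, `square_signal()`, `threshold()`,
  `power_threshold()`, `predict_peaks()`). The central result: a plain
  threshold creates alias peaks only around odd carrier multiples, while the
  *cubed* threshold ⌊x⌋₀³ fills in the even multiples and follows the alias
  up to exactly 3.5 carrier multiples.
- **A stochastic P-unit model** — an adapting leaky integrate-and-fire
  neuron driven through a dendritic low-pass by the rectified, exponentiated
  field, with a packaged table of nine fitted parameter sets
  (`punit_params()`, `simulate_punit()`, `load_param_table()`,
  `rebalance_bias()`, `baseline_stats()`).
- **Tuning-curve analysis** — binary spike trains, Gaussian-kernel firing
  rates, Welch spectra, frequency tuning f<sub>resp</sub>, amplitude tuning
  A<sub>resp</sub>, alias tracking f<sub>max</sub>, frequency sweeps and the
  threshold-exponent RMSE scan (`psd()`, `response_frequency()`,
  `response_amplitude()`, `fmax_range()`, `run_sweep()`,
  `rmse_exponent_scan()`).
- **Jamming-avoidance response (JAR) analysis** — spectrogram-based EOD
  frequency tracking on synthetic frequency-shifting recordings, the
  baseline/steady-state shift statistic, and the ±5 Hz stimulation protocol
  (`synth_jar_recording()`, `track_eod_frequency()`, `jar_shift()`,
  `jar_protocol_frequencies()`).

See the vignette `vignettes/mistuned-octave-envelopes.Rmd` for the model
equations, parameter conventions, and design choices.

## Worked example

A fish with f<sub>EOD</sub> = 668 Hz hears a 737 Hz stimulus at 20 %
contrast. The cubed-threshold cascade recovers the beat:

```r
library(punitbeats)

w  <- synth_superposition(668, 737, 0.2, rate = 40000, duration = 1)
ps <- psd(power_threshold(w, 3), nfft = length(w$samples), window = "rect")
response_frequency(ps, 668)   # strongest peak below f_EOD/2
#> [1] 69
expected_alias(737, 668)
#> [1] 69
```

69 Hz is the difference frequency Δf = 737 − 668 — the classical beat. The
same machinery works where no naive envelope extractor does: drive a fitted
P-unit model (cell 2018-06-25-ad, rebalanced to a cubed threshold) with a
stimulus at 2.1 × f<sub>EOD</sub>, an absolute difference frequency of
735 Hz, far above f<sub>EOD</sub>/2:

```r
m  <- load_param_table()[["2018-06-25-ad"]]
carrier <- synth_superposition(668, 668, 0, 40000, 1)
m3 <- rebalance_bias(m, 3, carrier, seed = 1)

stim <- synth_superposition(668, 2.1 * 668, 0.2, 40000, 2)
st   <- simulate_punit(m3, stim, seed = 1)
st
#> <spike_train> 1463 spikes over 2 s (mean rate 731.5 Hz)

r   <- kernel_rate(spikes_to_binary(st), 5e-4)
psr <- psd(r, rate = 40000, nfft = 4096, trim = 0.005)
response_frequency(psr, 668)
#> [1] 68.35938
expected_alias(2.1 * 668, 668)
#> [1] 66.8
```

The spike train's strongest spectral peak below f<sub>EOD</sub>/2 sits at
68.4 Hz — the 66.8 Hz alias of the 2.1 × carrier stimulus, to within one
9.77 Hz frequency bin. The firing rate is modulated at the slow envelope
frequency although the stimulus is more than an octave above the carrier;
with a plain threshold (`m` instead of `m3`) that peak is absent.

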