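---
title: "Extracting beat-like envelopes at mistuned octaves: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting beat-like envelopes at mistuned octaves: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(punitbeats)
```

## The problem

A wave-type electric fish emits a quasi-sinusoidal electric organ discharge
(EOD) at a carrier frequency $f_{EOD}$. A nearby conspecific's field, or an
experimental sine-wave stimulus at frequency $f_{stim}$ and relative
amplitude $\alpha$ (the *contrast*), superimposes with it:

$$x(t) = \cos(2\pi f_{EOD} t) + \alpha \cos(2\pi f_{stim} t).$$

For $f_{stim}$ close to $f_{EOD}$ this produces the classical *beat*: a slow
amplitude modulation at the difference frequency. But slow envelopes reappear
whenever $f_{stim}$ approaches any integer multiple of $f_{EOD}$ (*mistuned
octaves*), with a frequency given by the alias

$$f_{exp} = \bigl|f_{stim} - f_{EOD}\,\mathrm{round}(f_{stim}/f_{EOD})\bigr|,$$

so that $f_{EOD}/2$ plays the role of a Nyquist frequency. P-type
electroreceptor afferents (P-units), whose firing rate follows EOD amplitude
modulations, respond at exactly these alias frequencies over several carrier
multiples. The puzzle is mechanistic: the raw superposition's power spectrum
contains only the two original frequencies, so some nonlinearity must
*create* the envelope frequency before a low-pass stage and the spike
generator can encode it. This package implements the candidate
nonlinearities, an analytic prediction of the spectral peaks they generate, a
fitted stochastic P-unit model, the tuning-curve analysis, and the
jamming-avoidance-response (JAR) readout, entirely on synthetic signals.

## Envelope-extraction nonlinearities

Four candidate static operations are provided, all acting sample-wise on a
`waveform`:

* `analytic_envelope()` — magnitude of the analytic signal (Hilbert
  envelope). Correct for classical beats; at higher multiples it locks onto a
  fast modulation and misses the slow alias.
* `square_signal()` — produces a peak at the raw difference frequency
  $|f_{stim}-f_{EOD}|$ however large, again missing the alias structure.
* `threshold()` — half-wave rectification $\lfloor x \rfloor_0$. Creates
  alias peaks around *odd* carrier multiples and around zero, but none near
  two or four multiples.
* `power_threshold(w, p)` — $\lfloor x \rfloor_0^p$. For $p = 3$ the cubed
  threshold also fills in the even multiples; the alias is produced for all
  stimulus frequencies up to $3.5\,f_{EOD}$ and for none beyond (the
  package's sweep and the analytic prediction agree on this bound exactly).

### Analytic peak prediction

`predict_peaks()` implements the pulse-train approximation: rectification is
replaced by multiplication with a carrier-locked square wave
(`pulse_train()`), so the output spectrum is the convolution of the signal
spectrum (self-convolved twice for $p=3$) with the square-wave series — DC
$\tfrac12$ and odd harmonics $2/(\pi k)$ with alternating sign. The
derivation is carried out symbolically on signed frequency components with
real cosine coefficients:

```{r}
predict_peaks(500, 575, 0.2, p = 1)      # classical beat: one sub-band peak
head(predict_peaks(500, 1050, 0.2, p = 3), 3)  # octave alias at 0.1 f1
```

Numerical choices worth stating:

* **Coincident peaks** are merged when frequencies agree within
  $10^{-6} f_1$ and their *signed* coefficients are summed before taking the
  magnitude — this implements the rule that crossing spectral peaks (at
  $f_1/2$, $3f_1/2$, ...) add up, and yields the elevated amplitudes observed
  there.
* **Truncation**: nine odd square-wave harmonics by default; the $1/k$ decay
  makes further terms negligible below $f_1/2$.
* **Orders**: each component records how many stimulus factors (powers of
  $\alpha$) produced it. First-order components are the theory's branch
  structure; $\alpha^2$ and $\alpha^3$ terms are retained for completeness
  but are orders of magnitude weaker, and `alias_predicted()` counts only
  first-order peaks.
* **Validation**: the prediction is checked against a numerical FFT of the
  actual rectified signal; at $\alpha \le 0.05$ positions agree to the bin
  and amplitudes to better than 10 % (the residual error is the
  zero-crossing shift the approximation ignores, which grows with
  $\alpha$).

### The coverage bound at 3.5 multiples

The first-order alias peak below $f_1/2$ exists exactly for
$f_{stim} \le 3.5 f_{EOD}$: the reachable branch set is
$\{|k f_1 - f_2|\}$ with $k \in \{0, 1, 2, 3, 5, 7, \dots\}$ — $k = 4$ is
unreachable because the square wave has no even harmonics and the cubed
signal contributes only a $\pm 2 f_1$ shift. One boundary subtlety: at
exactly half-integer multiples the alias equals $f_1/2$ and crossing peaks
still produce it, so an isolated match recurs at $4.5\,f_{EOD}$. The
package therefore reports the *contiguous* coverage limit (the largest grid
ratio up to which every ratio follows the alias), which is 3.5 on a 0.05
grid, matching the theory.

## Sampled-signal conventions

The default sampling rate is 40 kHz, the digitization rate of the
electrophysiology rig the analysis settings are tied to. Carriers are
normalized to amplitude one; `synth_eod()` rescales a multi-harmonic
template so the *peak-to-peak* amplitude matches a unit cosine, following
the convention that the receiving fish's EOD has amplitude one. The
packaged `skewed_eod_template()` (amplitudes 1, 0.5, 0.25; phases 0, 3.2, 0
rad) is a synthetic stand-in for a real EOD — real harmonic coefficients
were not available — chosen once so the positive duty cycle is close to
2/3. That choice nulls the third harmonic of the derived pulse train, which
is the configuration in which a plain threshold loses the alias response at
the third carrier multiple while the cubed threshold keeps it; it also puts
energy at twice the fundamental, unlike the 50 % duty cycle of a pure
cosine.

`cycle_envelope()` connects per-carrier-cycle extrema piecewise-linearly; it
is a visualization/diagnostic device, not part of the analysis chain.

## Spectral analysis settings

Spike trains are binarized at 40 kHz (spike bins carry the value
$1/\Delta t$ so the integral is the spike count) and smoothed with Gaussian
kernels of $\sigma = 0.5$ ms or 2 ms — the physiological range of
post-synaptic potentials in the hindbrain target neurons. In the frequency
domain these kernels are Gaussian low-passes of width
$1/(2\pi\sigma) = 318$ Hz and 80 Hz; `kernel_bandwidth()` recomputes this
numerically from the sampled kernel.

Power spectra use Welch averaging with 4096-sample segments and 50 %
overlap; the first and last 5 ms of spike trains are excluded. The segment
window is not dictated by the analysis it reproduces, so the package uses a
Hann window with per-segment mean subtraction (constant detrend) and
documents that every quantitative check that needs bin-exact frequencies
uses a full-length rectangular FFT at integer-cycle frequencies instead —
peak *positions* at bin resolution are window-insensitive, which is all the
tuning statistics consume. `response_amplitude()` integrates the five bins
nearest the peak; on a bin-centered sinusoidal rate modulation of amplitude
$A$ this returns $A/\sqrt2$ exactly under the Hann scaling, a calibration
frozen in the tests.

`response_frequency()` searches $0 < f \le f_{EOD}/2$ (DC excluded:
rectification shifts the mean, which is not a rate modulation; the upper
edge is inclusive so that crossings at exactly $f_{EOD}/2$ are countable)
and returns the raw argmax bin without interpolation — sub-bin precision is
obtained by lengthening segments, not by interpolating. The alias-tracking
statistic `fmax_range()` sums stimulus-frequency bins
$(f_{i+1}-f_{i-1})/2$ where the squared relative deviation of response from
alias is below $5\times10^{-4}$; endpoints contribute one-sided
half-widths, a choice the interior-only formula leaves open. `round()` in
the alias is half-away-from-zero; the alias symmetry at half-integers makes
the tie-break immaterial.

## The P-unit model

The spike generator is a leaky integrate-and-fire neuron with
spike-frequency adaptation, driven through a dendritic low-pass:

$$\tau_m \dot V_m = -V_m + f(V_m) + \mu + \beta V_d - A + \sqrt{2D}\,\xi,
\qquad \tau_A \dot A = -A, \qquad
\tau_d \dot V_d = -V_d + \lfloor x \rfloor_0^{\,p}.$$

Threshold 1, reset 0, absolute refractoriness $t_{ref}$ implemented as a
hard clamp at reset. $f(V_m)$ is zero for the LIF or the exponential term
$\Delta_V e^{(V_m-1)/\Delta_V}$ (`eif_term()`, spike criterion
$V_m \ge 1 + 10\Delta_V$ as a finite blow-up cutoff; results are
insensitive to the cutoff's exact value). Integration is Euler–Maruyama at
$\Delta t = 1/\text{rate}$ (0.025 ms), with a Gaussian increment of
variance $2D\Delta t$ added to the numerator of the membrane update ($D$ in
ms, voltages dimensionless); the zero-noise firing rate matches the
closed-form interspike interval
$t_{ref} + \tau_m \ln\!\frac{\mu}{\mu-1}$ to under 1 % at this step, and
halving the step changes it by less than 1 %. Initial conditions are
$V_m = V_d = A = 0$ with a 500 ms cyclic warm-up discarded so adaptation
settles.

**Adaptation increment.** On each spike $A$ jumps by $\Delta_A/\tau_A$, not
by $\Delta_A$ directly. This is the package's deliberate convention: the
nine packaged parameter sets satisfy $(\mu + \beta/\pi - 1)/\Delta_A
\approx 0.97\,\mathrm{ms}^{-1}$ for every cell, and with a bare $\Delta_A$
jump they would all fire at 5–30 Hz — far outside the 64–530 Hz baseline
range of the P-units they were fitted to — and lose the envelope-encoding
contrast between exponents entirely. With the $\Delta_A/\tau_A$ jump
(dimensionally, the increment of $\tau_A A$) the models fire in the
phase-locked P-unit regime, show partial vector-strength locking well below
one, and reproduce the diagnostic behavior: at $f_{stim} = 2.1 f_{EOD}$ the
$p=3$ model places its strongest sub-band peak at the $0.1 f_{EOD}$ alias
while the $p=1$ model does not. The packaged parameters are used verbatim
and validated qualitatively at this level, not quantitatively against
recordings.

When the exponent is changed, `rebalance_bias()` restores the original
baseline rate by a scalar root find on $\mu$ (monotone in $\mu$); every
candidate evaluation reuses one seed so the objective is deterministic.

## Sweeps and the exponent scan

`run_sweep()` drives either a pure `threshold_cascade()` or a model across
a grid of stimulus frequencies (default 0.05–4.0 carrier multiples in 0.05
steps, contrast 0.2, trials of at least 0.5 s, matching the stimulation
protocol's trial lengths and contrasts) and assembles a `tuning_curve`.
`rmse_exponent_scan()` compares frequency- and amplitude-tuning curves
against reference curves across exponents $p$, after rebalancing the bias
at each $p$. Because the recorded cells' curves are not available as
numbers, the scan is exercised as a *parameter-recovery* experiment: the
reference is a simulated $p=3$ curve (different seed), and the amplitude
RMSE is verified to be minimized at $p=3$ — a deliberate substitution for
the recorded-population comparison, which is out of reach without the
deposited recordings. Test and acceptance runs use scaled problem sizes
(one model cell, 17-point grids, 0.5 s trials, exponents 1–4); these sizes
are stated here as the package's chosen operating point for the
self-recovery design.

## JAR analysis

`synth_jar_recording()` generates a multi-harmonic field whose fundamental
approaches $f_{EOD} + \text{shift}$ exponentially after onset (default time
constant 3 s, consistent with a response developing within about 10 s); the
phase is the integral of the instantaneous frequency, so the waveform is
continuous at onset. `track_eod_frequency()` mirrors the behavioral
analysis: spectrogram with 131072-sample segments and 50 % overlap (3.3 s
segments, 0.3 Hz bins at 40 kHz), frequency read from the *second*
harmonic — doubling the effective resolution — inside a ±50 Hz band around
twice the baseline estimate (the analysis it follows states no band; JAR
shifts are a few Hz, so a narrow band is safe), refined by parabolic
interpolation of log-power across three bins, then halved.
`jar_shift()` is the mean over 15–25 s post-onset minus the 10 s pre-onset
mean. Round trips over programmed shifts of 1–6 Hz recover the shift to
within 2 %; the residual is dominated by the exponential's remaining
approach deficit (≈0.2 %) and interpolation bias (≲0.01 Hz).
`jar_protocol_frequencies()` reproduces the stimulation protocol ($k
f_{EOD} - 5$ Hz for $k = 1..5$; 5 Hz for $k = 0$), and the package asserts
on the *prediction* side that the cubed-threshold envelope amplitude at the
5 Hz alias declines across multiples 1–3 — the trend behavioral shifts
follow — without claiming any behavioral numbers.

## What the synthetic data do and do not show

Everything here runs on synthesized signals: pure or multi-harmonic
carriers, noiseless superpositions, and noise only inside the neuron model.
Real recordings add measurement noise, nonstationary EOD frequencies,
electrode filtering, and cell-to-cell diversity that the nine fitted
parameter sets only sample. Passing tests therefore demonstrate the
*mechanistic* chain — which nonlinearity creates which spectral peaks, and
that a spiking encoder with realistic filtering can read them out — not a
quantitative fit to any recorded population. Statistics tied to the
recorded data (population correlations, the sensitive/insensitive split,
measured behavioral shift sizes) are deliberately out of scope.

## Known limitations

* Analytic peak amplitudes inherit the pulse-train approximation's
  $O(\alpha)$ error; at the experimental contrast 0.2 side-peak amplitudes
  deviate visibly even though positions remain exact.
* `predict_peaks()` supports $p \in \{1, 3\}$; other exponents are explored
  numerically through sweeps.
* The electroreceptor resonance (band-pass tuning to the carrier itself) is
  not modeled; the model's frequency axis is therefore valid for stimuli
  within the afferent's tuning range.
* With the packaged parameters the models operate near one spike per EOD
  cycle at baseline; absolute firing rates are not calibrated to individual
  recorded cells.
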