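# Synthetic electric-field signals: two-tone superpositions, multi-harmonic
# EOD-like carriers, SAM stimuli, and per-cycle envelopes.

#' Sampled waveform
#'
#' Container for a uniformly sampled, real-valued signal. Amplitudes are
#' dimensionless; by convention the carrier is normalized to amplitude one,
#' so a two-tone superposition with contrast `alpha` is bounded by
#' `1 + alpha` in absolute value.
#'
#' @param samples numeric vector of samples (dimensionless amplitude).
#' @param rate sampling rate in Hz.
#' @param f_carrier carrier (EOD) frequency in Hz, or `NULL` if not applicable.
#' @param f_stim stimulus frequency in Hz, or `NULL`.
#' @param contrast stimulus amplitude relative to the carrier amplitude
#'   (fraction), or `NULL`.
#'
#' @return An object of class `"waveform"`: a list with elements `samples`,
#'   `rate`, `f_carrier`, `f_stim`, `contrast`.
#' @seealso [synth_superposition()], [synth_eod()], [synth_sam()]
#' @export
waveform <- function(samples, rate, f_carrier = NULL, f_stim = NULL,
                     contrast = NULL) {
  stopifnot(is.numeric(samples), length(rate) == 1L, is.finite(rate), rate > 0)
  structure(list(samples = as.numeric(samples), rate = as.numeric(rate),
                 f_carrier = f_carrier, f_stim = f_stim, contrast = contrast),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %g Hz (%.4g s)\n",
              length(x$samples), x$rate, wf_duration(x)))
  if (!is.null(x$f_carrier)) cat(sprintf("  carrier: %g Hz\n", x$f_carrier))
  if (!is.null(x$f_stim))    cat(sprintf("  stimulus: %g Hz (contrast %g)\n",
                                         x$f_stim,
                                         if (is.null(x$contrast)) NA else x$contrast))
  invisible(x)
}

#' Time axis and duration of a waveform
#'
#' @param w a [waveform()].
#' @return `wf_time()` returns the vector of sample times in seconds (starting
#'   at 0); `wf_duration()` the duration in seconds.
#' @export
wf_time <- function(w) (seq_along(w$samples) - 1) / w$rate

#' @rdname wf_time
#' @export
wf_duration <- function(w) length(w$samples) / w$rate

check_nyquist <- function(f, rate, what = "frequency") {
  if (any(f >= rate / 2))
    stop(sprintf("%s (%g Hz) must be below the Nyquist frequency rate/2 = %g Hz",
                 what, max(f), rate / 2), call. = FALSE)
  invisible(TRUE)
}

#' Superposition of two cosine waves
#'
#' Builds the sampled signal `x(t) = cos(2 pi f1 t + phase1) +
#' alpha * cos(2 pi f2 t + phase2)`: a unit-amplitude carrier (the receiving
#' fish's EOD) plus a stimulus cosine of relative amplitude `alpha`
#' (the contrast). Beats and beat-like envelopes arise from this sum; its
#' power spectrum nevertheless contains only the two original frequencies.
#'
#' @param f1 carrier frequency (Hz).
#' @param f2 stimulus frequency (Hz).
#' @param alpha stimulus contrast, relative to the carrier amplitude.
#' @param rate sampling rate (Hz); 40 kHz by default.
#' @param duration duration (s).
#' @param phase1,phase2 initial phases (rad), 0 by default.
#' @return A [waveform()] with carrier/stimulus metadata.
#' @export
synth_superposition <- function(f1, f2, alpha, rate = 40000, duration = 1,
                                phase1 = 0, phase2 = 0) {
  stopifnot(duration > 0, alpha >= 0)
  check_nyquist(c(f1, f2), rate, "carrier/stimulus frequency")
  t <- (seq_len(round(rate * duration)) - 1) / rate
  x <- cos(2 * pi * f1 * t + phase1) + alpha * cos(2 * pi * f2 * t + phase2)
  waveform(x, rate, f_carrier = f1, f_stim = f2, contrast = alpha)
}

#' EOD harmonic template
#'
#' A small table of relative harmonic amplitudes and phases describing a
#' periodic EOD-like waveform. Amplitudes are normalized so the fundamental
#' has `a[1] = 1`.
#'
#' @param amplitudes numeric vector of harmonic amplitudes `a_k`, `k = 1..K`.
#' @param phases numeric vector of harmonic phases (rad), same length.
#' @return An object of class `"eod_template"`: a data frame with columns
#'   `k`, `amplitude`, `phase`.
#' @export
eod_template <- function(amplitudes, phases = numeric(length(amplitudes))) {
  stopifnot(length(amplitudes) >= 1, length(phases) == length(amplitudes),
            amplitudes[1] != 0)
  d <- data.frame(k = seq_along(amplitudes),
                  amplitude = amplitudes / amplitudes[1],
                  phase = phases)
  class(d) <- c("eod_template", "data.frame")
  d
}

#' Packaged skewed test template (synthetic)
#'
#' A three-harmonic synthetic stand-in for a real EOD waveform, constructed
#' so that the waveform spends about two thirds of each period above zero
#' (positive duty cycle close to 2/3). Its derived pulse train therefore has
#' energy at twice the fundamental and almost none at three times the
#' fundamental -- the configuration under which a plain half-wave
#' rectification loses the alias response at the third carrier multiple.
#' Harmonic amplitudes and phases of real fish were not available, so this
#' template is synthetic and used for testing only.
#'
#' @return An [eod_template()] with amplitudes `(1, 0.5, 0.25)` and phases
#'   `(0, 3.2, 0)` rad.
#' @export
skewed_eod_template <- function() {
  eod_template(c(1, 0.5, 0.25), c(0, 3.2, 0))
}

#' Multi-harmonic EOD-like carrier
#'
#' Sums the template's harmonics, `sum_k a_k cos(2 pi k f_eod t + phi_k)`,
#' and rescales the result so its peak-to-peak amplitude equals that of a
#' unit cosine (amplitude-one convention for the receiving fish's EOD).
#'
#' @param template an [eod_template()].
#' @param f_eod fundamental (EOD) frequency (Hz).
#' @inheritParams synth_superposition
#' @return A [waveform()] periodic with period `1/f_eod`.
#' @export
synth_eod <- function(template, f_eod, rate = 40000, duration = 1) {
  stopifnot(inherits(template, "eod_template"), duration > 0)
  check_nyquist(max(template$k) * f_eod, rate, "highest harmonic")
  t <- (seq_len(round(rate * duration)) - 1) / rate
  x <- numeric(length(t))
  for (i in seq_len(nrow(template)))
    x <- x + template$amplitude[i] *
      cos(2 * pi * template$k[i] * f_eod * t + template$phase[i])
  x <- x / ((max(x) - min(x)) / 2)
  waveform(x, rate, f_carrier = f_eod)
}

#' Sinusoidally amplitude-modulated (SAM) stimulus
#'
#' A carrier multiplied by `1 + alpha cos(2 pi f_am t)`. Unlike the two-tone
#' superposition, a SAM has three spectral peaks: the carrier `f1` and the
#' side bands `f1 - f_am` and `f1 + f_am`.
#'
#' @param f1 carrier frequency (Hz).
#' @param f_am modulation frequency (Hz); must be below `f1`.
#' @inheritParams synth_superposition
#' @return A [waveform()].
#' @export
synth_sam <- function(f1, f_am, alpha, rate = 40000, duration = 1) {
  stopifnot(duration > 0, f_am < f1)
  check_nyquist(f1 + f_am, rate, "upper side band")
  t <- (seq_len(round(rate * duration)) - 1) / rate
  x <- (1 + alpha * cos(2 * pi * f_am * t)) * cos(2 * pi * f1 * t)
  waveform(x, rate, f_carrier = f1, f_stim = f_am, contrast = alpha)
}

#' Per-cycle upper and lower envelope
#'
#' Connects the maxima (minima) of each carrier cycle by piecewise-linear
#' interpolation, sampled on the waveform's own time grid. This is a simple,
#' reproducible construction intended for visualization and qualitative
#' checks; spectral analyses should use the nonlinearity cascades instead.
#'
#' @param w a [waveform()] containing at least 3 carrier cycles.
#' @param f_carrier carrier frequency (Hz); defaults to `w$f_carrier`.
#' @return A list with numeric vectors `upper` and `lower`, same length as
#'   `w$samples`.
#' @export
cycle_envelope <- function(w, f_carrier = w$f_carrier) {
  stopifnot(inherits(w, "waveform"), !is.null(f_carrier))
  t <- wf_time(w)
  n_cyc <- floor(wf_duration(w) * f_carrier)
  if (n_cyc < 3) stop("waveform must contain at least 3 carrier cycles")
  cyc <- floor(t * f_carrier)
  keep <- which(cyc < n_cyc)
  idx <- split(keep, cyc[keep])
  up <- vapply(idx, function(i) i[which.max(w$samples[i])], integer(1))
  lo <- vapply(idx, function(i) i[which.min(w$samples[i])], integer(1))
  list(upper = approx(t[up], w$samples[up], xout = t, rule = 2)$y,
       lower = approx(t[lo], w$samples[lo], xout = t, rule = 2)$y)
}
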