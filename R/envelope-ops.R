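# Static nonlinearities and linear filters for envelope extraction, the
# pulse-train approximation, and analytic prediction of the spectral peaks
# generated by (exponentiated) half-wave rectification.

as_samples <- function(w) if (inherits(w, "waveform")) w$samples else as.numeric(w)

map_samples <- function(w, f) {
  if (inherits(w, "waveform")) { w$samples <- f(w$samples); w } else f(as.numeric(w))
}

#' Half-wave rectification (threshold)
#'
#' Sets all negative values of the signal to zero, keeping only the positive
#' half-waves -- the upper envelope survives, the lower one is discarded.
#' Known as ReLU in other fields.
#'
#' @param w a [waveform()] or numeric vector.
#' @return Same type as the input.
#' @export
threshold <- function(w) map_samples(w, function(x) pmax(x, 0))

#' Exponentiated half-wave rectification
#'
#' `max(x, 0)^p`. The exponent smooths the hard threshold; `p = 3` (a cubed
#' threshold) narrows the carrier half-waves enough to generate spectral
#' peaks at the slow envelope frequencies around even carrier multiples,
#' which a plain threshold (`p = 1`) misses.
#'
#' @param w a [waveform()] or numeric vector.
#' @param p positive exponent.
#' @return Same type as the input.
#' @export
power_threshold <- function(w, p) {
  stopifnot(length(p) == 1L, is.finite(p), p > 0)
  map_samples(w, function(x) pmax(x, 0)^p)
}

#' Squared signal
#'
#' Elementwise `x^2`. Squaring creates a spectral peak at the difference
#' frequency of a two-tone signal no matter how large that difference is, so
#' it cannot reproduce the aliasing structure of beat-like envelopes.
#'
#' @param w a [waveform()] or numeric vector.
#' @return Same type as the input; nonnegative samples.
#' @export
square_signal <- function(w) map_samples(w, function(x) x^2)

#' Hilbert (analytic-signal) envelope
#'
#' Magnitude of the analytic signal, computed via the FFT half-spectrum
#' construction. For a classical beat (stimulus near the carrier) this is
#' the slow amplitude modulation; near higher carrier multiples it instead
#' tracks a fast modulation and does not recover the slow envelope.
#'
#' @param w a [waveform()] or numeric vector.
#' @return Numeric vector of envelope values, same length as the input.
#' @export
analytic_envelope <- function(w) {
  x <- as_samples(w)
  n <- length(x)
  stopifnot(n > 1)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(fft(x) * h, inverse = TRUE) / n)
}

#' Centered running average
#'
#' Moving mean over a window of `window` seconds (one carrier period by
#' default), which attenuates the carrier and keeps only frequency
#' components below the carrier frequency. Edges are padded by replicating
#' the first/last complete mean.
#'
#' @param w a [waveform()] (or numeric vector, in which case `rate` and
#'   `window` must be given).
#' @param window averaging window in seconds; defaults to one carrier period.
#' @param rate sampling rate (Hz), taken from the waveform if available.
#' @return Numeric vector, same length as the input.
#' @export
running_average <- function(w, window = NULL, rate = NULL) {
  x <- as_samples(w)
  if (is.null(rate)) rate <- w$rate
  if (is.null(window)) {
    if (is.null(w$f_carrier)) stop("window not given and waveform has no carrier frequency")
    window <- 1 / w$f_carrier
  }
  n_win <- round(window * rate)
  if (n_win < 2) stop("averaging window must span at least 2 samples")
  if (n_win > length(x)) stop("averaging window longer than the signal")
  y <- as.numeric(stats::filter(x, rep(1 / n_win, n_win), sides = 2))
  ok <- which(!is.na(y))
  y[seq_len(ok[1] - 1)] <- y[ok[1]]
  y[seq((ok[length(ok)] + 1), length.out = length(y) - ok[length(ok)])] <- y[ok[length(ok)]]
  y
}

#' Carrier-locked pulse train
#'
#' Binary signal that is 1 wherever the carrier is nonnegative and 0
#' elsewhere. For a pure cosine carrier the duty cycle is 1/2 and the
#' spectrum has peaks at zero and at odd carrier multiples only; skewed
#' multi-harmonic carriers give other duty cycles and even-harmonic content.
#'
#' @param carrier a [waveform()] or numeric vector.
#' @return Same type as the input, with samples in `{0, 1}`.
#' @export
pulse_train <- function(carrier) map_samples(carrier, function(x) as.numeric(x >= 0))

#' Pulse-train approximation of the threshold
#'
#' Multiplies the signal with the carrier-locked [pulse_train()],
#' approximating half-wave rectification of the superposition. The
#' approximation is exact for vanishing stimulus contrast and degrades as
#' the stimulus shifts the zero crossings of the carrier.
#'
#' @param w signal [waveform()].
#' @param carrier carrier [waveform()] on the same time grid.
#' @return A [waveform()] (or numeric vector, following `w`).
#' @export
pulse_train_approx <- function(w, carrier) {
  xs <- as_samples(w); cs <- as_samples(carrier)
  if (length(xs) != length(cs)) stop("signal and carrier are not on the same grid")
  if (inherits(w, "waveform") && inherits(carrier, "waveform") &&
      !isTRUE(all.equal(w$rate, carrier$rate)))
    stop("signal and carrier sampling rates differ")
  p <- as.numeric(cs >= 0)
  map_samples(w, function(x) x * p)
}

# -- analytic peak prediction -------------------------------------------------

# Components are tables of signed frequencies with real (cosine-phase)
# complex-exponential coefficients; `order` counts the number of stimulus
# factors (powers of alpha) in each term.
merge_comps <- function(d, tol) {
  key <- round(d$freq / tol)
  coef <- tapply(d$coef, key, sum)
  ord <- tapply(d$order, key, min)
  freq <- tapply(d$freq, key, function(f) f[1])
  data.frame(freq = as.numeric(freq), coef = as.numeric(coef),
             order = as.numeric(ord))
}

convolve_comps <- function(a, b, tol) {
  merge_comps(data.frame(freq = c(outer(a$freq, b$freq, "+")),
                         coef = c(outer(a$coef, b$coef, "*")),
                         order = c(outer(a$order, b$order, "+"))), tol)
}

#' Predicted spectral peaks of the (cubed) threshold
#'
#' Analytic prediction of the peaks in the spectrum of an exponentiated
#' half-wave rectified two-tone signal, via the pulse-train approximation:
#' the signal (raised to the exponent by spectral self-convolution) is
#' multiplied by a carrier-locked square wave, i.e. its spectrum is
#' convolved with the square-wave Fourier series (DC 1/2; odd harmonics
#' `2/(pi k)` with alternating sign). Components whose frequencies coincide
#' (within `1e-6 * f1`) are summed with their signs, implementing the rule
#' that crossing spectral peaks add up.
#'
#' @param f1 carrier frequency (Hz).
#' @param f2 stimulus frequency (Hz).
#' @param alpha stimulus contrast (small for the approximation to be good).
#' @param p threshold exponent; 1 or 3.
#' @param n_harmonics number of odd square-wave harmonics retained.
#' @param f_max report peaks at frequencies in `(0, f_max]`; default `f1/2`,
#'   the band in which firing-rate modulations are read out.
#' @return A data frame of class `"peak_prediction"` with columns
#'   `freq` (Hz), `amp_rel` (one-sided cosine amplitude relative to `alpha`),
#'   `amp` (absolute amplitude), and `order` (number of stimulus factors in
#'   the lowest-order contribution; `order = 0` rows are carrier-only peaks,
#'   `order >= 1` rows depend on the stimulus). Sorted by frequency.
#' @seealso [alias_predicted()]
#' @export
predict_peaks <- function(f1, f2, alpha, p = 1, n_harmonics = 9,
                          f_max = f1 / 2) {
  stopifnot(f1 > 0, f2 >= 0, alpha > 0, n_harmonics >= 1)
  if (!p %in% c(1, 3))
    stop("analytic peak prediction supports p = 1 or p = 3 only")
  tol <- 1e-6 * f1
  sig <- data.frame(freq = c(f1, -f1, f2, -f2),
                    coef = c(0.5, 0.5, alpha / 2, alpha / 2),
                    order = c(0, 0, 1, 1))
  if (p == 3) sig <- convolve_comps(convolve_comps(sig, sig, tol), sig, tol)
  ks <- seq(1, by = 2, length.out = n_harmonics)
  pulse <- data.frame(freq = c(0, ks * f1, -ks * f1),
                      coef = c(0.5, rep((-1)^(seq_along(ks) - 1) / (pi * ks), 2)),
                      order = 0)
  res <- convolve_comps(sig, pulse, tol)
  res$freq <- abs(res$freq)
  res <- merge_comps(res, tol)
  res <- res[res$freq > tol / 2 & res$freq <= f_max + tol & abs(res$coef) > 1e-12, ]
  # one-sided cosine amplitude: +f and -f conjugate halves were merged onto
  # |freq|, so the merged coefficient already sums both halves
  out <- data.frame(freq = res$freq, amp_rel = abs(res$coef) / alpha,
                    amp = abs(res$coef), order = res$order)
  out <- out[order(out$freq), ]
  rownames(out) <- NULL
  class(out) <- c("peak_prediction", "data.frame")
  out
}

#' Is the expected alias peak predicted?
#'
#' Convenience predicate: does the analytic prediction contain a
#' first-order (proportional to `alpha`) peak at the expected alias
#' frequency `|f2 - round(f2/f1) f1|` below `f1/2`? Higher-order terms
#' (proportional to `alpha^2` and beyond) are not counted: they are orders
#' of magnitude weaker and never dominate the band.
#'
#' @inheritParams predict_peaks
#' @param min_amp minimum relative amplitude for a peak to count.
#' @return `TRUE` or `FALSE`.
#' @export
alias_predicted <- function(f1, f2, alpha = 0.01, p = 3, n_harmonics = 9,
                            min_amp = 1e-9) {
  fa <- expected_alias(f2, f1)
  if (fa <= 1e-6 * f1 || fa > f1 / 2 + 1e-6 * f1) return(FALSE)
  pk <- predict_peaks(f1, f2, alpha, p = p, n_harmonics = n_harmonics)
  pk <- pk[pk$order == 1 & pk$amp_rel >= min_amp, ]
  any(abs(pk$freq - fa) < 1e-6 * f1)
}
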