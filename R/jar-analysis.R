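# Jamming-avoidance response (JAR) analysis: spectrogram-based EOD
# frequency tracking, baseline/steady-state shift computation, protocol
# frequencies, and a synthetic frequency-shifting recording generator.

#' EOD frequency trace
#'
#' Time course of the instantaneous EOD frequency estimate, with the
#' stimulus onset time attached.
#'
#' @param time times (s), increasing.
#' @param freq EOD frequency estimates (Hz), positive.
#' @param onset stimulus onset time (s), or `NA`.
#' @return A data frame of class `"frequency_trace"` with columns `time`,
#'   `freq` and attribute `onset`.
#' @export
frequency_trace <- function(time, freq, onset = NA_real_) {
  stopifnot(length(time) == length(freq), !is.unsorted(time), all(freq > 0))
  d <- data.frame(time = time, freq = freq)
  attr(d, "onset") <- onset
  class(d) <- c("frequency_trace", "data.frame")
  d
}

#' Track the EOD frequency of a recording
#'
#' Computes a spectrogram (segment length `nfft`, 50 percent overlap, Hann
#' window) and estimates the EOD frequency per segment from the peak of the
#' second harmonic -- the second harmonic is favored because it doubles the
#' frequency resolution of the few-Hz JAR shifts. The search is restricted
#' to a band around twice the (estimated or given) baseline frequency, the
#' peak is refined by parabolic interpolation of the log-power across three
#' bins, and the result is divided by two.
#'
#' @param recording a [waveform()] of the fish's field, long enough for at
#'   least one segment.
#' @param nominal_f approximate EOD fundamental (Hz); estimated from the
#'   first segment's strongest peak when `NULL`.
#' @param nfft spectrogram segment length (samples); the default 131072 at
#'   40 kHz gives ~3.3 s segments and ~0.3 Hz bins.
#' @param overlap segment overlap fraction.
#' @param band_halfwidth half-width (Hz) of the search band around twice
#'   the baseline frequency.
#' @param onset stimulus onset (s) recorded on the returned trace.
#' @return A [frequency_trace()] with one estimate per segment (times are
#'   segment centers).
#' @export
track_eod_frequency <- function(recording, nominal_f = NULL, nfft = 131072,
                                overlap = 0.5, band_halfwidth = 50,
                                onset = NA_real_) {
  stopifnot(inherits(recording, "waveform"))
  fs <- recording$rate
  if (length(recording$samples) < nfft)
    stop("recording shorter than one spectrogram segment")
  sg <- signal::specgram(recording$samples, n = nfft, Fs = fs,
                         overlap = round(nfft * overlap))
  P <- Mod(sg$S)^2
  f <- as.numeric(sg$f)
  tt <- as.numeric(sg$t) + nfft / (2 * fs)  # segment centers
  if (is.null(nominal_f)) {
    i0 <- which(f > 10)
    nominal_f <- f[i0][which.max(P[i0, 1])]
  }
  band <- which(abs(f - 2 * nominal_f) <= band_halfwidth)
  if (length(band) < 3)
    stop("second-harmonic search band is empty at this resolution")
  if (max(P[band, 1]) < 1e-6 * max(P[, 1]))
    stop("no second-harmonic energy in the search band; cannot track the EOD")
  est <- vapply(seq_len(ncol(P)), function(j) {
    i <- band[which.max(P[band, j])]
    i <- min(max(i, 2L), length(f) - 1L)
    lp <- log(pmax(P[(i - 1):(i + 1), j], .Machine$double.xmin))
    denom <- lp[1] - 2 * lp[2] + lp[3]
    delta <- if (denom < 0) 0.5 * (lp[1] - lp[3]) / denom else 0
    (f[i] + delta * (f[2] - f[1])) / 2
  }, numeric(1))
  frequency_trace(tt, est, onset = onset)
}

#' Baseline-to-steady-state JAR frequency shift
#'
#' Mean EOD frequency within 15 to 25 s after stimulus onset minus the mean
#' within the 10 s right before onset.
#'
#' @param trace a [frequency_trace()].
#' @param onset stimulus onset (s); defaults to the trace's attribute.
#' @return Frequency shift (Hz).
#' @export
jar_shift <- function(trace, onset = attr(trace, "onset")) {
  stopifnot(inherits(trace, "frequency_trace"))
  if (is.na(onset)) stop("stimulus onset unknown")
  pre <- trace$freq[trace$time >= onset - 10 & trace$time < onset]
  post <- trace$freq[trace$time >= onset + 15 & trace$time <= onset + 25]
  if (length(pre) < 3 || length(post) < 3)
    stop("trace does not cover the 10 s baseline and the 15-25 s steady-state windows")
  mean(post) - mean(pre)
}

#' JAR protocol stimulus frequencies
#'
#' The stimulation protocol places the stimulus 5 Hz below the k-th
#' multiple of the fish's EOD frequency for `k = 1..5`, and at an absolute
#' 5 Hz for `k = 0`.
#'
#' @param f_eod the fish's EOD frequency (Hz).
#' @param k multiple, 0 to 5; vectorized.
#' @return Stimulus frequency (Hz).
#' @export
jar_protocol_frequencies <- function(f_eod, k) {
  stopifnot(all(k >= 0), all(k <= 5), all(k == round(k)))
  ifelse(k == 0, 5, k * f_eod - 5)
}

#' Synthetic frequency-shifting EOD recording
#'
#' Generates a multi-harmonic EOD-like waveform whose instantaneous
#' fundamental frequency follows `f_eod` before `onset` and approaches
#' `f_eod + shift` exponentially with the given time constant afterwards.
#' The waveform is built by integrating the instantaneous frequency, so the
#' phase (and hence the signal) is continuous at onset. This is a synthetic
#' stand-in for behavioral recordings, used to exercise the tracking and
#' shift analysis end to end.
#'
#' @param f_eod baseline EOD frequency (Hz).
#' @param shift steady-state frequency shift (Hz).
#' @param onset stimulus onset (s).
#' @param time_constant exponential approach time constant (s).
#' @param template an [eod_template()]; defaults to a fundamental plus a
#'   0.5-amplitude second harmonic (tracking requires second-harmonic
#'   energy).
#' @param rate sampling rate (Hz).
#' @param duration total duration (s); the default covers the 15-25 s
#'   steady-state analysis window.
#' @param phase initial phase of the fundamental (rad).
#' @return A [waveform()].
#' @export
synth_jar_recording <- function(f_eod, shift, onset = 10, time_constant = 3,
                                template = NULL, rate = 40000,
                                duration = onset + 26, phase = 0) {
  stopifnot(f_eod > 0, onset > 0, time_constant > 0, duration > onset)
  if (is.null(template)) template <- eod_template(c(1, 0.5), c(0, 0))
  check_nyquist(max(template$k) * (f_eod + abs(shift)), rate, "highest harmonic")
  t <- (seq_len(round(rate * duration)) - 1) / rate
  finst <- rep(f_eod, length(t))
  post <- t >= onset
  finst[post] <- f_eod + shift * (1 - exp(-(t[post] - onset) / time_constant))
  ph <- phase + 2 * pi * cumsum(finst) / rate
  x <- numeric(length(t))
  for (i in seq_len(nrow(template)))
    x <- x + template$amplitude[i] *
      cos(template$k[i] * ph + template$phase[i])
  x <- x / ((max(x) - min(x)) / 2)
  waveform(x, rate, f_carrier = f_eod)
}
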