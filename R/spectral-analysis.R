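# Response-analysis pipeline: binary spike trains, Gaussian-kernel firing
# rates, Welch power spectra, frequency/amplitude tuning and alias tracking.

#' Spike train
#'
#' Ordered spike times on a fixed-duration trial.
#'
#' @param times numeric vector of spike times (s), strictly increasing,
#'   within `[0, duration)`.
#' @param duration trial duration (s).
#' @return An object of class `"spike_train"`.
#' @export
spike_train <- function(times, duration) {
  times <- as.numeric(times)
  stopifnot(duration > 0, all(times >= 0), all(times < duration),
            !is.unsorted(times, strictly = TRUE))
  structure(list(times = times, duration = as.numeric(duration)),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes over %g s (mean rate %.1f Hz)\n",
              length(x$times), x$duration, length(x$times) / x$duration))
  invisible(x)
}

#' Binary representation of a spike train
#'
#' Bins the spike times with step `1/rate`; spike bins get the value `rate`
#' (so the time integral of the series equals the spike count) and all other
#' bins are zero.
#'
#' @param st a [spike_train()].
#' @param rate analysis sampling rate (Hz); 40 kHz by default.
#' @return Numeric vector of length `round(duration * rate)`.
#' @export
spikes_to_binary <- function(st, rate = 40000) {
  stopifnot(inherits(st, "spike_train"))
  n <- round(st$duration * rate)
  b <- numeric(n)
  idx <- floor(st$times * rate) + 1
  if (anyDuplicated(idx))
    stop("two spikes fall into one time bin (refractory violation at this rate)")
  b[idx] <- rate
  b
}

#' Gaussian-kernel firing rate
#'
#' Convolves a binary spike series with a Gaussian kernel of standard
#' deviation `sigma` (truncated at 6 sigma, unit sum), yielding a
#' time-resolved firing rate in Hz whose integral preserves the spike
#' count. `sigma = 0` returns the series unchanged. In the frequency domain
#' the kernel is a Gaussian low-pass of standard deviation `1/(2 pi sigma)`,
#' mimicking the post-synaptic potential of the afferent's target neuron.
#'
#' @param binary numeric series (e.g. from [spikes_to_binary()]).
#' @param sigma kernel standard deviation (s).
#' @param rate sampling rate of the series (Hz).
#' @return Numeric vector, same length as `binary`.
#' @export
kernel_rate <- function(binary, sigma, rate = 40000) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(as.numeric(binary))
  h <- ceiling(6 * sigma * rate)
  k <- dnorm((-h:h) / rate, 0, sigma)
  k <- k / sum(k)
  y <- convolve(c(numeric(h), binary, numeric(h)), rev(k), type = "filter")
  as.numeric(y)
}

#' Frequency-domain width of the Gaussian kernel
#'
#' Numerically computes the standard deviation of the magnitude spectrum of
#' the sampled Gaussian kernel used by [kernel_rate()]. For a kernel of
#' width `sigma` this is `1/(2 pi sigma)` (318 Hz for 0.5 ms, 80 Hz for
#' 2 ms).
#'
#' @param sigma kernel standard deviation (s).
#' @param rate sampling rate (Hz).
#' @param n FFT length (zero-padded).
#' @return Frequency-domain standard deviation (Hz).
#' @export
kernel_bandwidth <- function(sigma, rate = 40000, n = 2^15) {
  stopifnot(sigma > 0)
  h <- ceiling(6 * sigma * rate)
  stopifnot(2 * h + 1 <= n)
  k <- dnorm((-h:h) / rate, 0, sigma)
  k <- k / sum(k)
  kk <- numeric(n)
  kk[seq_len(2 * h + 1)] <- k
  w <- Mod(fft(kk))
  f <- c(0:(n / 2), -(n / 2 - 1):-1) / n * rate
  sqrt(sum(w * f^2) / sum(w))
}

#' Welch power spectral density
#'
#' One-sided averaged periodogram from `nfft`-sample segments with the given
#' overlap. Each segment is mean-subtracted (constant detrend) and windowed
#' (Hann by default; `"rect"` gives a plain rectangular window, which with
#' `nfft = length(x)` reduces to a single full-length periodogram). For a
#' firing-rate series in Hz the density has units Hz^2/Hz.
#'
#' @param x a numeric series, [waveform()], or [spike_train()].
#' @param rate sampling rate (Hz); taken from the object when available.
#' @param nfft segment length in samples.
#' @param overlap segment overlap as a fraction of `nfft`.
#' @param window `"hann"` or `"rect"`.
#' @param trim seconds to drop from each end before the analysis (5 ms for
#'   spike trains, matching the exclusion of onset/offset edges).
#' @param detrend subtract each segment's mean before windowing.
#' @param ... passed to methods.
#' @return An object of class `"power_spectrum"`: list with `freq` (Hz,
#'   starting at 0), `power` (density), `df` (resolution, Hz), `rate`.
#' @export
psd <- function(x, ...) UseMethod("psd")

#' @rdname psd
#' @export
psd.waveform <- function(x, ...) psd(x$samples, rate = x$rate, ...)

#' @rdname psd
#' @export
psd.spike_train <- function(x, rate = 40000, trim = 0.005, ...) {
  psd(spikes_to_binary(x, rate), rate = rate, trim = trim, ...)
}

#' @rdname psd
#' @export
psd.default <- function(x, rate, nfft = 4096, overlap = 0.5,
                        window = c("hann", "rect"), trim = 0,
                        detrend = TRUE, ...) {
  window <- match.arg(window)
  x <- as.numeric(x)
  if (trim > 0) {
    nt <- round(trim * rate)
    if (2 * nt >= length(x)) stop("series shorter than twice the trim")
    x <- x[(nt + 1):(length(x) - nt)]
  }
  n <- length(x)
  if (n < nfft) stop("series shorter than one segment after trimming")
  w <- if (window == "hann") signal::hanning(nfft) else rep(1, nfft)
  step <- max(1, round(nfft * (1 - overlap)))
  starts <- seq(1, n - nfft + 1, by = step)
  acc <- numeric(nfft %/% 2 + 1)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nfft - 1)]
    if (detrend) seg <- seg - mean(seg)
    X <- fft(seg * w)
    acc <- acc + Mod(X[seq_len(nfft %/% 2 + 1)])^2
  }
  dens <- acc / length(starts) / (rate * sum(w^2))
  scale2 <- rep(2, length(dens))
  scale2[1] <- 1
  if (nfft %% 2 == 0) scale2[length(dens)] <- 1
  dens <- dens * scale2
  structure(list(freq = (seq_along(dens) - 1) * rate / nfft, power = dens,
                 df = rate / nfft, rate = rate),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d bins, df = %g Hz, 0..%g Hz\n",
              length(x$freq), x$df, max(x$freq)))
  invisible(x)
}

#' Decibel transform of a power spectrum
#'
#' `10 log10(power / ref)`, with the spectrum maximum as the default
#' reference, for plotting parity across conditions.
#'
#' @param ps a `"power_spectrum"` or numeric vector of densities.
#' @param ref reference density.
#' @return Numeric vector (dB).
#' @export
to_decibel <- function(ps, ref = NULL) {
  p <- if (inherits(ps, "power_spectrum")) ps$power else as.numeric(ps)
  if (is.null(ref)) ref <- max(p)
  10 * log10(p / ref)
}

#' Response frequency
#'
#' Frequency of the strongest spectral peak in `(0, f_eod/2]` -- the
#' frequency of the firing-rate modulation, with half the carrier frequency
#' playing the role of a Nyquist frequency. The DC bin is excluded because
#' rectification shifts the mean without modulating the rate.
#'
#' @param ps a `"power_spectrum"`.
#' @param f_eod carrier (EOD) frequency (Hz).
#' @return Frequency (Hz) of the maximum density bin in the band.
#' @export
response_frequency <- function(ps, f_eod) {
  band <- ps$freq > 0 & ps$freq <= f_eod / 2 + 1e-9 * f_eod
  if (!any(band)) stop("spectrum has no bins in (0, f_eod/2]")
  ps$freq[band][which.max(ps$power[band])]
}

#' Response amplitude
#'
#' Square root of the integral of the power spectrum over the five
#' frequencies closest to the peak frequency -- the amplitude of the
#' firing-rate modulation, in Hz.
#'
#' @param ps a `"power_spectrum"`.
#' @param fresp peak frequency (Hz), e.g. from [response_frequency()].
#' @param n_bins number of nearest bins integrated (5).
#' @return Modulation amplitude (Hz for a firing-rate spectrum).
#' @export
response_amplitude <- function(ps, fresp, n_bins = 5) {
  if (fresp < min(ps$freq) || fresp > max(ps$freq))
    stop("fresp outside the spectrum's frequency range")
  idx <- order(abs(ps$freq - fresp))[seq_len(n_bins)]
  sqrt(sum(ps$power[idx]) * ps$df)
}

#' Expected alias frequency
#'
#' `|fstim - f_eod * round(fstim/f_eod)|`, the sub-`f_eod/2` image of the
#' stimulus frequency, with rounding half away from zero (the choice is
#' immaterial by symmetry: at half-integer multiples both neighbors give
#' `f_eod/2`).
#'
#' @param fstim stimulus frequency (Hz); vectorized.
#' @param f_eod carrier (EOD) frequency (Hz).
#' @return Alias frequency in `[0, f_eod/2]` (Hz).
#' @export
expected_alias <- function(fstim, f_eod) {
  stopifnot(f_eod > 0)
  r <- fstim / f_eod
  k <- sign(r) * floor(abs(r) + 0.5)
  abs(fstim - f_eod * k)
}

#' Tuning curve container
#'
#' Per-stimulus-frequency records of the response frequency `fresp`, the
#' response amplitude `aresp`, and the expected alias `fexp`.
#'
#' @param fstim_hz stimulus frequencies (Hz).
#' @param fresp_hz response frequencies (Hz).
#' @param aresp_hz response amplitudes (Hz).
#' @param f_eod carrier frequency (Hz), stored as an attribute.
#' @return A data frame of class `"tuning_curve"` with columns `fstim_hz`,
#'   `fstim_rel`, `fresp_hz`, `aresp_hz`, `fexp_hz`.
#' @export
tuning_curve <- function(fstim_hz, fresp_hz, aresp_hz, f_eod) {
  stopifnot(length(fstim_hz) == length(fresp_hz),
            length(fstim_hz) == length(aresp_hz), f_eod > 0)
  d <- data.frame(fstim_hz = fstim_hz, fstim_rel = fstim_hz / f_eod,
                  fresp_hz = fresp_hz, aresp_hz = aresp_hz,
                  fexp_hz = expected_alias(fstim_hz, f_eod))
  d <- d[order(d$fstim_hz), ]
  rownames(d) <- NULL
  attr(d, "f_eod") <- f_eod
  class(d) <- c("tuning_curve", "data.frame")
  d
}

#' Alias-following range (fmax)
#'
#' Cumulative range of stimulus frequencies over which the response
#' frequency matches the expected alias: bins `(fstim[i+1] - fstim[i-1])/2`
#' are summed over all stimulus frequencies whose squared relative deviation
#' `((fresp - fexp)/f_eod)^2` is below `tol`; the endpoints contribute
#' one-sided half-widths.
#'
#' @param tc a [tuning_curve()], sorted by stimulus frequency.
#' @param tol match tolerance on the squared relative deviation (0.0005).
#' @return Cumulative matched stimulus-frequency range (Hz).
#' @export
fmax_range <- function(tc, tol = 5e-4) {
  stopifnot(inherits(tc, "tuning_curve"))
  f_eod <- attr(tc, "f_eod")
  n <- nrow(tc)
  if (n < 3) stop("need at least 3 tuning-curve points")
  f <- tc$fstim_hz
  widths <- c((f[2] - f[1]) / 2,
              (f[3:n] - f[1:(n - 2)]) / 2,
              (f[n] - f[n - 1]) / 2)
  match <- ((tc$fresp_hz - tc$fexp_hz) / f_eod)^2 < tol
  sum(widths[match])
}
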