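# Stimulus-frequency sweeps through nonlinearity cascades or P-unit models,
# population tuning curves, and the exponent-scan RMSE comparison.

#' Sweep configuration
#'
#' Settings for a stimulus-frequency sweep: the carrier frequency, the grid
#' of stimulus frequencies in multiples of the carrier, the contrast, and
#' the analysis parameters.
#'
#' @param f_eod carrier (EOD) frequency (Hz).
#' @param rel_freqs stimulus frequencies in multiples of `f_eod`.
#' @param alpha stimulus contrast.
#' @param n_trials trials per stimulus frequency (model sweeps).
#' @param duration trial duration (s), at least 0.5 s.
#' @param sigma Gaussian firing-rate kernel width (s).
#' @param rate sampling/integration rate (Hz).
#' @param nfft PSD segment length (samples).
#' @param seed master seed; per-trial seeds are derived deterministically
#'   from it and the frequency/trial indices.
#' @return An object of class `"sweep_config"`.
#' @export
sweep_config <- function(f_eod = 668, rel_freqs = seq(0.05, 4, by = 0.05),
                         alpha = 0.2, n_trials = 1, duration = 0.5,
                         sigma = 5e-4, rate = 40000, nfft = 4096, seed = 1) {
  stopifnot(f_eod > 0, all(rel_freqs >= 0), alpha >= 0, n_trials >= 1,
            duration >= 0.5)
  structure(list(f_eod = f_eod, rel_freqs = rel_freqs, alpha = alpha,
                 n_trials = n_trials, duration = duration, sigma = sigma,
                 rate = rate, nfft = nfft, seed = seed),
            class = "sweep_config")
}

#' Static nonlinearity cascade
#'
#' A spike-free reference pathway: the two-tone superposition is passed
#' through the exponentiated threshold and analyzed directly, standing in
#' for the receptor-synapse nonlinearity without a spike generator.
#'
#' @param p threshold exponent.
#' @return An object of class `"threshold_cascade"`.
#' @export
threshold_cascade <- function(p = 3) {
  stopifnot(p > 0)
  structure(list(p = p), class = "threshold_cascade")
}

#' Run a stimulus-frequency sweep
#'
#' For every stimulus frequency on the grid: synthesize the superposition
#' of the carrier and the stimulus cosine, obtain the response (the
#' nonlinearity output for a [threshold_cascade()], or Gaussian-kernel
#' firing rates of simulated spike trains for a [punit_params()] model),
#' compute its power spectrum, and extract the response frequency, response
#' amplitude and expected alias. Model trials are averaged at the spectrum
#' level.
#'
#' @param object a [threshold_cascade()] or [punit_params()].
#' @param cfg a [sweep_config()].
#' @param ... unused.
#' @return A [tuning_curve()].
#' @export
run_sweep <- function(object, cfg, ...) UseMethod("run_sweep")

#' @rdname run_sweep
#' @export
run_sweep.threshold_cascade <- function(object, cfg, ...) {
  stopifnot(inherits(cfg, "sweep_config"))
  fr <- ar <- numeric(length(cfg$rel_freqs))
  for (i in seq_along(cfg$rel_freqs)) {
    f2 <- cfg$rel_freqs[i] * cfg$f_eod
    w <- synth_superposition(cfg$f_eod, f2, cfg$alpha, cfg$rate, cfg$duration)
    ps <- psd(power_threshold(w, object$p), nfft = cfg$nfft)
    fr[i] <- response_frequency(ps, cfg$f_eod)
    ar[i] <- response_amplitude(ps, fr[i])
  }
  tuning_curve(cfg$rel_freqs * cfg$f_eod, fr, ar, cfg$f_eod)
}

#' @rdname run_sweep
#' @export
run_sweep.punit_params <- function(object, cfg, ...) {
  stopifnot(inherits(cfg, "sweep_config"))
  fr <- ar <- numeric(length(cfg$rel_freqs))
  for (i in seq_along(cfg$rel_freqs)) {
    f2 <- cfg$rel_freqs[i] * cfg$f_eod
    w <- synth_superposition(cfg$f_eod, f2, cfg$alpha, cfg$rate, cfg$duration)
    acc <- NULL
    for (tr in seq_len(cfg$n_trials)) {
      st <- simulate_punit(object, w,
                           seed = (cfg$seed + 7919L * i + tr) %% .Machine$integer.max)
      r <- kernel_rate(spikes_to_binary(st, cfg$rate), cfg$sigma, cfg$rate)
      ps <- psd(r, rate = cfg$rate, nfft = cfg$nfft, trim = 0.005)
      acc <- if (is.null(acc)) ps else { acc$power <- acc$power + ps$power; acc }
    }
    acc$power <- acc$power / cfg$n_trials
    fr[i] <- response_frequency(acc, cfg$f_eod)
    ar[i] <- response_amplitude(acc, fr[i])
  }
  tuning_curve(cfg$rel_freqs * cfg$f_eod, fr, ar, cfg$f_eod)
}

#' Population summary of tuning curves
#'
#' Pointwise median and interquartile range of the response frequencies and
#' amplitudes across a list of tuning curves sharing the same stimulus
#' grid.
#'
#' @param curves list of [tuning_curve()]s on one grid.
#' @return A data frame with columns `fstim_hz`, `fstim_rel`, and median /
#'   lower / upper quartiles of `fresp` and `aresp`.
#' @export
population_summary <- function(curves) {
  stopifnot(length(curves) >= 1, all(vapply(curves, inherits, TRUE, "tuning_curve")))
  grid <- curves[[1]]$fstim_hz
  for (cv in curves)
    if (!isTRUE(all.equal(cv$fstim_hz, grid)))
      stop("tuning curves do not share a stimulus-frequency grid")
  fr <- sapply(curves, function(cv) cv$fresp_hz)
  ar <- sapply(curves, function(cv) cv$aresp_hz)
  if (is.null(dim(fr))) { fr <- matrix(fr, nrow = length(grid)); ar <- matrix(ar, nrow = length(grid)) }
  q <- function(m, p) apply(m, 1, quantile, probs = p, names = FALSE)
  data.frame(fstim_hz = grid, fstim_rel = curves[[1]]$fstim_rel,
             fresp_med = q(fr, 0.5), fresp_q1 = q(fr, 0.25), fresp_q3 = q(fr, 0.75),
             aresp_med = q(ar, 0.5), aresp_q1 = q(ar, 0.25), aresp_q3 = q(ar, 0.75))
}

rmse <- function(a, b) sqrt(mean((a - b)^2))

#' Threshold-exponent scan
#'
#' For each model and each exponent on the grid, rebalances the bias
#' current to the model's native baseline rate, simulates the tuning curve,
#' and computes root mean squared errors against every reference curve --
#' separately for frequency tuning (in multiples of the carrier) and
#' amplitude tuning (Hz).
#'
#' @param models list of [punit_params()].
#' @param reference list of reference [tuning_curve()]s on the same grid as
#'   the sweep configuration produces.
#' @param p_grid threshold exponents to scan.
#' @param cfg a [sweep_config()].
#' @param rebalance_duration simulation length per bias evaluation (s).
#' @return A data frame of class `"exponent_scan"` with columns `model`,
#'   `reference`, `p`, `rmse_freq` (relative-frequency RMSE), `rmse_amp`
#'   (amplitude RMSE, Hz).
#' @export
rmse_exponent_scan <- function(models, reference, p_grid, cfg,
                               rebalance_duration = 8) {
  stopifnot(all(vapply(models, inherits, TRUE, "punit_params")),
            all(vapply(reference, inherits, TRUE, "tuning_curve")))
  carrier <- synth_superposition(cfg$f_eod, cfg$f_eod, 0, cfg$rate, 1)
  rows <- list()
  for (mi in seq_along(models)) {
    m <- models[[mi]]
    target <- {
      st <- simulate_punit(m, carrier, seed = cfg$seed)
      length(st$times) / st$duration
    }
    for (p in p_grid) {
      mp <- if (p == m$p) m else
        rebalance_bias(m, p, carrier, target_rate = target, seed = cfg$seed,
                       duration = rebalance_duration)
      curve <- run_sweep(mp, cfg)
      for (ri in seq_along(reference)) {
        ref <- reference[[ri]]
        if (!isTRUE(all.equal(ref$fstim_hz, curve$fstim_hz)))
          stop("reference curve grid does not match the sweep grid")
        rows[[length(rows) + 1]] <- data.frame(
          model = if (is.na(m$cell)) as.character(mi) else m$cell,
          reference = ri, p = p,
          rmse_freq = rmse(curve$fresp_hz / cfg$f_eod, ref$fresp_hz / cfg$f_eod),
          rmse_amp = rmse(curve$aresp_hz, ref$aresp_hz))
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("exponent_scan", "data.frame")
  out
}

#' Median RMSE per exponent
#'
#' Medians (with quartiles) of the frequency- and amplitude-tuning RMSEs
#' across all model-reference pairings, per threshold exponent.
#'
#' @param scan an `"exponent_scan"` from [rmse_exponent_scan()].
#' @return A data frame with one row per exponent.
#' @export
summarize_exponent_scan <- function(scan) {
  stopifnot(inherits(scan, "exponent_scan"))
  ps <- sort(unique(scan$p))
  do.call(rbind, lapply(ps, function(p) {
    s <- scan[scan$p == p, ]
    data.frame(p = p,
               rmse_freq_med = median(s$rmse_freq),
               rmse_freq_q1 = quantile(s$rmse_freq, 0.25, names = FALSE),
               rmse_freq_q3 = quantile(s$rmse_freq, 0.75, names = FALSE),
               rmse_amp_med = median(s$rmse_amp),
               rmse_amp_q1 = quantile(s$rmse_amp, 0.25, names = FALSE),
               rmse_amp_q3 = quantile(s$rmse_amp, 0.75, names = FALSE))
  }))
}
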