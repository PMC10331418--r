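# Stochastic adapting leaky integrate-and-fire P-unit model with dendritic
# low-pass prefilter and exponentiated threshold input, plus baseline
# statistics and the packaged table of nine fitted parameter sets.

#' P-unit model parameters
#'
#' The eight fitted constants of the adapting leaky integrate-and-fire
#' P-unit model plus the threshold exponent `p` and an optional exponential
#' spike-initiation softness `delta_v`. The spike threshold is fixed at 1
#' and the reset at 0 (voltages are dimensionless); all time constants are
#' in ms as printed in the fitted-parameter table.
#'
#' The model is
#' \deqn{\tau_m \dot V_m = -V_m + f(V_m) + \mu + \beta V_d - A + \sqrt{2D}\,\xi}
#' \deqn{\tau_A \dot A = -A, \qquad \tau_d \dot V_d = -V_d + \lfloor x \rfloor_0^p}
#' with unit-intensity white noise `xi` and `f = 0` for the plain LIF. On a
#' spike the voltage resets, is clamped for `t_ref`, and the adaptation
#' variable `A` jumps by `delta_a / tau_a` (see the methods vignette for
#' this convention).
#'
#' @param beta input gain (dimensionless).
#' @param tau_m membrane time constant (ms).
#' @param mu bias current (dimensionless).
#' @param noise_d noise strength D (ms).
#' @param tau_a adaptation time constant (ms).
#' @param delta_a adaptation increment (dimensionless, see above).
#' @param tau_d dendritic low-pass time constant (ms).
#' @param t_ref absolute refractory period (ms).
#' @param p threshold exponent applied to the rectified stimulus.
#' @param delta_v exponential integrate-and-fire softness in `[0.001, 0.1]`,
#'   or `NULL` for the plain LIF.
#' @param cell cell identifier.
#' @return An object of class `"punit_params"`.
#' @export
punit_params <- function(beta, tau_m, mu, noise_d, tau_a, delta_a, tau_d,
                         t_ref, p = 1, delta_v = NULL, cell = NA_character_) {
  stopifnot(tau_m > 0, tau_a > 0, tau_d > 0, t_ref >= 0, noise_d >= 0, p > 0)
  if (!is.null(delta_v))
    stopifnot(delta_v >= 0.001, delta_v <= 0.1)
  structure(list(beta = beta, tau_m = tau_m, mu = mu, noise_d = noise_d,
                 tau_a = tau_a, delta_a = delta_a, tau_d = tau_d,
                 t_ref = t_ref, p = p, delta_v = delta_v, cell = cell),
            class = "punit_params")
}

#' @export
print.punit_params <- function(x, ...) {
  cat(sprintf("<punit_params> cell %s (p = %g%s)\n", x$cell, x$p,
              if (is.null(x$delta_v)) "" else sprintf(", EIF dV = %g", x$delta_v)))
  cat(sprintf("  beta = %g, tau_m = %g ms, mu = %g, D = %g ms\n",
              x$beta, x$tau_m, x$mu, x$noise_d))
  cat(sprintf("  tau_A = %g ms, delta_A = %g, tau_d = %g ms, t_ref = %g ms\n",
              x$tau_a, x$delta_a, x$tau_d, x$t_ref))
  invisible(x)
}

#' Packaged fitted parameter table
#'
#' The nine P-unit parameter sets shipped with the package, fitted (with
#' `p = 1`) to the baseline activity and amplitude-step responses of nine
#' recorded cells.
#'
#' @param as `"params"` for a named list of [punit_params()], `"data.frame"`
#'   for the raw table.
#' @return A named list of `"punit_params"` or a data frame with columns
#'   `cell`, `beta`, `tau_m_ms`, `mu`, `D_ms`, `tau_A_ms`, `delta_A`,
#'   `tau_d_ms`, `t_ref_ms`.
#' @export
load_param_table <- function(as = c("params", "data.frame")) {
  as <- match.arg(as)
  path <- system.file("extdata", "punit_model_parameters.csv",
                      package = "punitbeats", mustWork = TRUE)
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (as == "data.frame") return(d)
  out <- lapply(seq_len(nrow(d)), function(i)
    punit_params(beta = d$beta[i], tau_m = d$tau_m_ms[i], mu = d$mu[i],
                 noise_d = d$D_ms[i], tau_a = d$tau_A_ms[i],
                 delta_a = d$delta_A[i], tau_d = d$tau_d_ms[i],
                 t_ref = d$t_ref_ms[i], cell = d$cell[i]))
  names(out) <- d$cell
  out
}

#' Exponential spike-initiation term
#'
#' `delta_v * exp((v - 1) / delta_v)`, the drift contribution of the
#' exponential integrate-and-fire model with softness `delta_v` and
#' threshold 1. The plain LIF is the `delta_v -> 0` limit, where the term
#' vanishes below threshold.
#'
#' @param v membrane voltage (dimensionless); vectorized.
#' @param delta_v softness parameter.
#' @return Drift contribution, same length as `v`.
#' @export
eif_term <- function(v, delta_v) {
  stopifnot(delta_v > 0)
  delta_v * exp((v - 1) / delta_v)
}

#' Simulate the P-unit model
#'
#' Euler-Maruyama integration at the stimulus sampling rate (step
#' `1/rate`). The stimulus is rectified and raised to the exponent
#' `params$p` before entering the dendritic low-pass compartment. The model
#' is warmed up on a cyclic continuation of the stimulus for `warmup`
#' seconds (discarded) so the adaptation settles; initial conditions are
#' `V_m = V_d = A = 0`.
#'
#' @param params a [punit_params()].
#' @param stimulus a [waveform()] sampled at the integration rate.
#' @param seed integer seed for the noise, or `NULL` to use the current RNG
#'   state.
#' @param warmup discarded warm-up (s).
#' @return A [spike_train()] spanning the stimulus duration.
#' @export
simulate_punit <- function(params, stimulus, seed = NULL, warmup = 0.5) {
  stopifnot(inherits(params, "punit_params"), inherits(stimulus, "waveform"))
  if (!is.null(seed)) set.seed(seed)
  times <- punit_lif_cpp(stimulus$samples, stimulus$rate,
                         params$beta, params$tau_m, params$mu, params$noise_d,
                         params$tau_a, params$delta_a, params$tau_d,
                         params$t_ref, params$p,
                         if (is.null(params$delta_v)) 0 else params$delta_v,
                         !is.null(params$delta_v),
                         as.integer(round(warmup * stimulus$rate)))
  spike_train(times, wf_duration(stimulus))
}

#' Baseline statistics of a spike train
#'
#' Firing rate (count/duration), coefficient of variation of the
#' inter-spike intervals, serial correlation of consecutive intervals at
#' lag one, and the vector strength of spike coupling to the carrier,
#' `VS = |mean(exp(2 pi i f t_spike))|`.
#'
#' @param st a [spike_train()].
#' @param carrier a [waveform()] with a carrier frequency, or the carrier
#'   frequency itself (Hz).
#' @return An object of class `"baseline_stats"`: list with `rate` (Hz),
#'   `cv`, `rho1`, `vs`.
#' @export
baseline_stats <- function(st, carrier) {
  stopifnot(inherits(st, "spike_train"))
  f <- if (inherits(carrier, "waveform")) carrier$f_carrier else as.numeric(carrier)
  if (is.null(f)) stop("carrier waveform has no carrier frequency")
  if (length(st$times) < 3)
    stop("need at least 3 spikes for interval statistics")
  isi <- diff(st$times)
  structure(list(rate = length(st$times) / st$duration,
                 cv = sd(isi) / mean(isi),
                 rho1 = if (length(isi) >= 3)
                   cor(isi[-length(isi)], isi[-1]) else NA_real_,
                 vs = Mod(mean(exp(2i * pi * f * st$times)))),
            class = "baseline_stats")
}

#' @export
print.baseline_stats <- function(x, ...) {
  cat(sprintf("<baseline_stats> rate %.1f Hz, CV %.3f, rho1 %.3f, VS %.3f\n",
              x$rate, x$cv, x$rho1, x$vs))
  invisible(x)
}

#' Rebalance the bias current after changing the threshold exponent
#'
#' When the threshold exponent is modified, the bias current `mu` is
#' re-adjusted so the model recovers its original baseline firing rate
#' (measured on the plain carrier). The adjustment is a scalar root find on
#' the simulated baseline rate, which is monotonically increasing in `mu`;
#' every rate evaluation reuses the same seed so the objective is
#' deterministic.
#'
#' @param params a [punit_params()].
#' @param new_p the new threshold exponent.
#' @param carrier baseline carrier [waveform()] (the plain EOD).
#' @param target_rate target baseline rate (Hz); defaults to the rate of
#'   `params` at its current exponent on this carrier.
#' @param seed seed used for every rate evaluation.
#' @param duration simulation length per evaluation (s).
#' @param tol relative rate tolerance (0.02 = 2 percent).
#' @return A [punit_params()] with exponent `new_p` and adjusted `mu`.
#' @export
rebalance_bias <- function(params, new_p, carrier, target_rate = NULL,
                           seed = 1, duration = 8, tol = 0.02) {
  stopifnot(inherits(params, "punit_params"))
  if (new_p == params$p && is.null(target_rate)) return(params)
  rate_at <- function(mu, p) {
    pp <- params; pp$mu <- mu; pp$p <- p
    st <- simulate_punit(pp, carrier, seed = seed)
    length(st$times) / st$duration
  }
  if (is.null(target_rate)) target_rate <- rate_at(params$mu, params$p)
  if (target_rate <= 0) stop("target baseline rate must be positive")
  obj <- function(mu) rate_at(mu, new_p) - target_rate
  span <- max(10, abs(params$mu))
  root <- uniroot(obj, interval = c(params$mu - span, params$mu + span),
                  extendInt = "upX", tol = 1e-3 * span, maxiter = 60)
  out <- params
  out$mu <- root$root
  out$p <- new_p
  got <- rate_at(out$mu, new_p)
  if (abs(got - target_rate) > tol * target_rate)
    stop(sprintf("rebalanced rate %.1f Hz misses target %.1f Hz by more than %g%%",
                 got, target_rate, 100 * tol))
  out
}
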