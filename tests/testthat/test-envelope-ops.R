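test_that("rectification nonlinearities have their closed-form means", {
  w <- synth_superposition(500, 500, 0, duration = 1)
  # half-wave rectified unit cosine has mean 1/pi (the kink at the zero
  # crossings limits the Riemann-sum accuracy at 80 samples per period)
  expect_equal(mean(threshold(w)$samples), 1 / pi, tolerance = 1e-3)
  # idempotence and elementwise definition
  expect_identical(threshold(threshold(c(-1, 0.5))), c(0, 0.5))
  # cubed rectified cosine has mean 2/(3 pi)
  expect_equal(mean(power_threshold(w, 3)$samples), 2 / (3 * pi),
               tolerance = 1e-4)
  # p = 1 reduces to the plain threshold
  x <- rnorm(100)
  expect_equal(power_threshold(x, 1), threshold(x))
  expect_error(power_threshold(x, 0), "p > 0")

  # squaring: cos^2 has DC 1/2 and one peak at 2f
  s <- square_signal(w)
  expect_true(all(s$samples >= 0))
  expect_equal(mean(s$samples), 0.5, tolerance = 1e-9)
  expect_identical(count_peaks(s$samples), 1L)
  expect_equal(dominant_freq(s$samples, 40000), 1000)
})

test_that("squaring puts the peak at the raw difference frequency, not the alias", {
  w <- synth_superposition(500, 3.05 * 500, 0.2, duration = 1)
  s <- square_signal(w)
  A <- amp_spectrum(s$samples - mean(s$samples))
  # peak at |f2 - f1| = 2.05 f1, nothing at the slow 0.05 f1 envelope frequency
  expect_gt(amp_at(A, 1025), 0.05)
  expect_lt(amp_at(A, 25), 1e-9)
})

test_that("the analytic envelope tracks beats but not mistuned-octave envelopes", {
  w <- synth_superposition(500, 500, 0, duration = 0.5)
  env <- analytic_envelope(w)
  expect_equal(env[1000:19000], rep(1, 18001), tolerance = 1e-6)
  expect_true(all(env >= abs(w$samples) - 1e-9))

  env <- analytic_envelope(synth_superposition(500, 550, 0.2, duration = 1))
  expect_equal(dominant_freq(env, 40000), 50)
  # near twice the carrier the analytic envelope is fast, not the 50 Hz alias
  env <- analytic_envelope(synth_superposition(500, 1050, 0.2, duration = 1))
  expect_equal(dominant_freq(env, 40000), 550)
})

test_that("running averages isolate slow envelope components only where they exist", {
  w <- synth_superposition(500, 500, 0, duration = 0.5)
  expect_lt(max(abs(running_average(w))), 1e-6)

  # threshold passes the beat envelope at 1.1 f1 ...
  w <- synth_superposition(500, 550, 0.2, duration = 1)
  ra <- running_average(threshold(w))
  A <- amp_spectrum(ra[2001:38000] - mean(ra[2001:38000]))
  a_beat_p1 <- max(A[round(50 * 0.9):round(50 * 1.1)])
  expect_gt(a_beat_p1, 0.01)

  # ... but not at 2.05 f1, where only the cubed threshold does
  w <- synth_superposition(500, 1025, 0.2, duration = 1)
  core <- 2001:38000
  ra1 <- running_average(threshold(w))[core]
  ra3 <- running_average(power_threshold(w, 3))[core]
  f_env <- 25 * (length(core) / 40000)  # envelope bin in the trimmed window
  a1 <- Mod(fft(ra1 - mean(ra1)))[round(f_env) + 1]
  a3 <- Mod(fft(ra3 - mean(ra3)))[round(f_env) + 1]
  expect_lt(a1, 0.05 * a3)

  expect_error(running_average(w, window = 2), "longer than the signal")
})

test_that("pulse trains have the square-wave structure and track carrier skew", {
  w <- synth_superposition(500, 500, 0, duration = 1)
  pt <- pulse_train(w)
  expect_equal(mean(pt$samples), 0.5, tolerance = 1e-3)
  A <- amp_spectrum(pt$samples - mean(pt$samples))
  # odd multiples present with 2/(pi k) amplitudes, even multiples absent
  expect_equal(amp_at(A, 500), 2 / pi, tolerance = 1e-2)
  expect_equal(amp_at(A, 1500), 2 / (3 * pi), tolerance = 1e-2)
  expect_lt(amp_at(A, 1000), 1e-3)

  # skewed multi-harmonic carrier: duty > 1/2 and second-multiple peak appears
  eod <- synth_eod(skewed_eod_template(), 500, 40000, 1)
  pts <- pulse_train(eod)
  expect_gt(mean(pts$samples), 0.6)
  As <- amp_spectrum(pts$samples - mean(pts$samples))
  expect_gt(amp_at(As, 1000), 0.2)
})

test_that("the pulse-train approximation converges to the threshold as contrast vanishes", {
  f1 <- 500
  carrier <- synth_superposition(f1, f1, 0, duration = 0.5)
  # alpha = 0: identical to thresholding the carrier
  expect_equal(pulse_train_approx(carrier, carrier)$samples,
               threshold(carrier)$samples, tolerance = 1e-12)
  rel_l2 <- function(alpha) {
    w <- synth_superposition(f1, 1.15 * f1, alpha, duration = 0.5)
    a <- pulse_train_approx(w, carrier)$samples
    b <- threshold(w)$samples
    sqrt(sum((a - b)^2) / sum(b^2))
  }
  expect_lt(rel_l2(0.01), 0.02)
  # at alpha = 0.2 the shifted zero crossings make the error clearly larger
  expect_gt(rel_l2(0.2), 5 * rel_l2(0.01))
  expect_gt(rel_l2(0.2), 0.02)
  expect_error(pulse_train_approx(synth_superposition(500, 575, 0.1, duration = 0.2),
                                  carrier), "grid")
})

test_that("analytic peak predictions match the worked branch structure", {
  # p = 1, f2 = 1.15 f1: a single sub-f1/2 peak at the difference frequency
  pk <- predict_peaks(500, 575, 0.2, p = 1)
  stim <- pk[pk$order >= 1, ]
  expect_identical(nrow(stim), 1L)
  expect_equal(stim$freq, 75)
  expect_equal(stim$amp_rel, 1 / pi, tolerance = 1e-9)

  # p = 1, f2 = 2.05 f1: thresholding creates nothing below f1/2
  pk <- predict_peaks(500, 1025, 0.2, p = 1)
  expect_identical(nrow(pk[pk$order >= 1, ]), 0L)

  # p = 3, f2 = 2.1 f1: the |2 f1 - f2| branch fills in the alias
  pk <- predict_peaks(500, 1050, 0.2, p = 3)
  expect_true(any(pk$order == 1 & abs(pk$freq - 50) < 1e-6))

  # crossing peaks at f2 = 1.5 f1 add up to an elevated amplitude
  at_alias <- function(r) {
    pk <- predict_peaks(500, r * 500, 0.05, p = 3)
    fa <- expected_alias(r * 500, 500)
    sum(pk$amp_rel[pk$order == 1 & abs(pk$freq - fa) < 1e-6])
  }
  expect_gt(at_alias(1.5), 1.3 * at_alias(1.45))

  expect_error(predict_peaks(500, 575, 0.2, p = 2), "p = 1 or p = 3")
})

test_that("predicted peaks match a numerical FFT oracle at small contrast", {
  f1 <- 500; alpha <- 0.05
  for (p in c(1, 3)) for (r in c(1.15, 2.1, 3.05)) {
    w <- synth_superposition(f1, r * f1, alpha, duration = 1)
    y <- power_threshold(w, p)$samples
    A <- amp_spectrum(y - mean(y))
    pk <- predict_peaks(f1, r * f1, alpha, p = p)
    pk <- pk[pk$order >= 1 & pk$amp_rel > 0.005, ]
    if (nrow(pk) == 0) {
      # prediction says the sub-f1/2 band is empty of stimulus peaks:
      # the measured band must be near the numerical floor
      expect_lt(max(A[2:250]), 0.01 * alpha)
    } else {
      # positions are exact bins here; amplitudes within 10 percent
      meas <- amp_at(A, pk$freq) / alpha
      expect_lt(max(abs(meas - pk$amp_rel) / pk$amp_rel), 0.1)
    }
  }
})

test_that("predicted alias amplitudes decay across carrier multiples and stop at 3.5", {
  f1 <- 500
  alias_amp <- function(r, p = 3) {
    pk <- predict_peaks(f1, r * f1, 0.01, p = p)
    fa <- expected_alias(r * f1, f1)
    sum(pk$amp_rel[pk$order == 1 & abs(pk$freq - fa) < 1e-6])
  }
  # monotone decay of the alias peak across successive multiples
  a <- vapply(c(1.1, 2.1, 3.1), alias_amp, numeric(1))
  expect_true(all(diff(a) < 0))
  a1 <- vapply(c(1.15, 3.05), alias_amp, numeric(1), p = 1)
  expect_true(all(diff(a1) < 0))

  # coverage bound: first-order alias predicted up to exactly 3.5 multiples
  rs <- seq(0.05, 4.45, by = 0.05)
  rs <- rs[abs(rs - round(rs)) > 1e-9]
  ok <- vapply(rs, function(r) alias_predicted(f1, r * f1, p = 3), logical(1))
  expect_true(all(ok[rs <= 3.5]))
  expect_false(any(ok[rs > 3.5]))
})
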