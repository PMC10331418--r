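test_that("the packaged parameter table matches the printed fits", {
  d <- load_param_table(as = "data.frame")
  expect_identical(nrow(d), 9L)
  params <- load_param_table()
  expect_length(params, 9)
  expect_equal(params[["2018-06-25-ad"]]$tau_d, 1.88)
  # median row of the printed table
  expect_equal(median(d$beta), 286.1)
  expect_equal(median(d$tau_m_ms), 1.74)
  expect_equal(median(d$mu), -31.84)
  expect_equal(median(d$D_ms), 0.17)
  expect_equal(median(d$tau_A_ms), 96.35)
  expect_equal(median(d$delta_A), 50.7)
  expect_equal(median(d$tau_d_ms), 4.08)
  expect_equal(median(d$t_ref_ms), 1.09)
})

test_that("the noiseless LIF reproduces the closed-form interspike interval", {
  # ISI = t_ref + tau_m log(mu / (mu - 1)) for constant drive mu > 1
  pp <- punit_params(beta = 0, tau_m = 5, mu = 2, noise_d = 0, tau_a = 100,
                     delta_a = 0, tau_d = 1, t_ref = 1)
  silent <- waveform(numeric(2 * 40000), 40000)
  st <- simulate_punit(pp, silent)
  rate <- length(st$times) / st$duration
  expect_equal(rate, 1000 / (1 + 5 * log(2)), tolerance = 0.01)

  # dt-convergence: halving the step changes the rate by < 1 percent
  silent2 <- waveform(numeric(2 * 80000), 80000)
  st2 <- simulate_punit(pp, silent2)
  expect_equal(length(st2$times) / st2$duration, rate, tolerance = 0.01)

  # subthreshold bias: no spikes
  pp$mu <- 0.5
  expect_length(simulate_punit(pp, silent)$times, 0)
})

test_that("simulations honor the refractory period and are reproducible", {
  m <- load_param_table()[["2018-06-25-ad"]]
  carrier <- synth_superposition(668, 668, 0, 40000, 1)
  st <- simulate_punit(m, carrier, seed = 1)
  expect_gt(length(st$times), 100)
  expect_gte(min(diff(st$times)) * 1000, m$t_ref - 1e-9)
  # same seed, same spikes; different seed, different spikes
  st2 <- simulate_punit(m, carrier, seed = 1)
  expect_identical(st$times, st2$times)
  st3 <- simulate_punit(m, carrier, seed = 2)
  expect_false(identical(st$times, st3$times))
  # zero noise: deterministic regardless of seed
  m0 <- m; m0$noise_d <- 0
  expect_identical(simulate_punit(m0, carrier, seed = 5)$times,
                   simulate_punit(m0, carrier, seed = 99)$times)
})

test_that("the exponential spike-initiation term behaves as specified", {
  expect_equal(eif_term(1, 0.01), 0.01)
  expect_equal(eif_term(1, 0.1), 0.1)
  v <- seq(0, 1.2, by = 0.01)
  expect_true(all(diff(eif_term(v, 0.02)) > 0))
  expect_lt(eif_term(0.9, 0.001), 1e-40)
  # an EIF model runs and spikes
  pp <- punit_params(beta = 0, tau_m = 5, mu = 2, noise_d = 0, tau_a = 100,
                     delta_a = 0, tau_d = 1, t_ref = 1, delta_v = 0.01)
  st <- simulate_punit(pp, waveform(numeric(40000), 40000))
  expect_gt(length(st$times), 100)
})

test_that("baseline statistics recover rate, ISI variability, and phase locking", {
  # homogeneous Poisson train: CV ~ 1, rho1 ~ 0
  set.seed(42)
  t <- cumsum(rexp(5000, 200))
  st <- spike_train(t[t < 24], 24)
  bs <- baseline_stats(st, 668)
  expect_equal(bs$rate, length(st$times) / 24)
  expect_equal(bs$cv, 1, tolerance = 0.05)
  expect_lt(abs(bs$rho1), 0.05)

  # perfectly periodic train: CV = 0; locked to one phase: VS = 1
  reg <- spike_train(seq(0, 0.999, by = 1 / 668), 1)
  bs <- baseline_stats(reg, 668)
  expect_equal(bs$cv, 0, tolerance = 1e-9)
  expect_equal(bs$vs, 1, tolerance = 1e-9)
  # uniform phases: VS near 0
  set.seed(7)
  unif <- spike_train(sort(runif(4000, 0, 0.999)), 1)
  expect_lt(baseline_stats(unif, 668)$vs, 0.05)

  # a fitted cell phase locks partially to the carrier: 0 < VS < 1
  m <- load_param_table()[["2018-06-25-ad"]]
  carrier <- synth_superposition(668, 668, 0, 40000, 2)
  bs <- baseline_stats(simulate_punit(m, carrier, seed = 3), carrier)
  expect_gt(bs$vs, 0.05)
  expect_lt(bs$vs, 0.99)

  expect_error(baseline_stats(spike_train(c(0.1, 0.2), 1), 668), "3 spikes")
})

test_that("spike-frequency adaptation acts as a high-pass on amplitude steps", {
  pp <- unlocked_params()
  rate <- 40000
  stim <- waveform(c(rep(0.1, rate), rep(0.2, 2 * rate)), rate)
  st <- simulate_punit(pp, stim)
  onset <- sum(st$times >= 1 & st$times < 1.05) / 0.05
  steady <- sum(st$times >= 2.5) / 0.5
  expect_gt(onset, 1.5 * steady)
})

test_that("rebalancing the bias restores the baseline rate for new exponents", {
  m <- load_param_table()[["2012-12-20-ae"]]
  carrier <- synth_superposition(668, 668, 0, 40000, 1)
  # no-op when the exponent is unchanged
  expect_identical(rebalance_bias(m, m$p, carrier), m)

  st <- simulate_punit(m, carrier, seed = 11, warmup = 0.5)
  target <- length(st$times) / st$duration
  for (p in c(0.5, 3)) {
    mp <- rebalance_bias(m, p, carrier, seed = 11, duration = 4)
    expect_equal(mp$p, p)
    stp <- simulate_punit(mp, carrier, seed = 11, warmup = 0.5)
    got <- length(stp$times) / stp$duration
    expect_equal(got, target, tolerance = 0.06)
  }

  # baseline rate is monotonically increasing in the bias current
  rates <- vapply(c(-40, -20, 0, 20), function(mu) {
    mm <- m; mm$mu <- mu
    stm <- simulate_punit(mm, carrier, seed = 11)
    length(stm$times) / stm$duration
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
})
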