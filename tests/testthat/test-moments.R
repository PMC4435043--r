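test_that("stationary moments follow the closed form", {
  sm <- stationary_moments(0, 0.16, tau_m = 26, u0 = -65.5)
  expect_equal(sm$mean, -65.5)
  expect_equal(sm$variance, 2.08)
  sm2 <- stationary_moments(0.12, 0.16, tau_m = 26, u0 = -65.5)
  expect_equal(sm2$mean, -62.38)
  expect_equal(sm2$variance, 2.08)
  expect_error(stationary_moments(0, 0.16, tau_m = -1, u0 = -65.5), "tau_m")
  expect_error(stationary_moments(0, 0, tau_m = 26, u0 = -65.5), "sigma2_0")
})

test_that("rates map to moments by the diffusion approximation", {
  z <- rates_to_moments(tibble::tibble(lam_E = 0, lam_I = 0))
  expect_equal(z$mu, 0)
  expect_equal(z$sigma2, 0)
  m <- rates_to_moments(tibble::tibble(lam_E = 7.7636, lam_I = 8.1556),
                        a_E = 0.11, a_I = 0.09)
  expect_equal(m$mu, 0.12, tolerance = 1e-3)
  expect_equal(m$sigma2, 0.16, tolerance = 1e-3)
  # balanced symmetric input has zero drift and variance 2 a^2 x
  s <- rates_to_moments(tibble::tibble(lam_E = 3, lam_I = 3),
                        a_E = 0.1, a_I = 0.1)
  expect_equal(s$mu, 0)
  expect_equal(s$sigma2, 2 * 0.1^2 * 3)
  expect_error(rates_to_moments(tibble::tibble(lam_E = -1, lam_I = 0)),
               "non-negative")
})

test_that("moment inversion is the closed-form inverse with clipping", {
  z <- moments_to_rates(tibble::tibble(mu = 0, sigma2 = 0))
  expect_equal(z$lam_E, 0)
  expect_equal(z$lam_I, 0)
  # closed-form inversion at the reference unstimulated statistics:
  # lam_E = (0.16 + 0.09*0.12) / (0.11*0.20), lam_I = (0.16 - 0.11*0.12) / (0.09*0.20)
  r <- moments_to_rates(tibble::tibble(mu = 0.12, sigma2 = 0.16),
                        a_E = 0.11, a_I = 0.09)
  expect_equal(r$lam_E, 0.1708 / 0.022, tolerance = 1e-12)
  expect_equal(r$lam_I, 0.1468 / 0.018, tolerance = 1e-12)
  expect_false(r$clipped_E || r$clipped_I)
  # strongly negative drift with tiny variance drives lam_E negative -> clip
  neg <- moments_to_rates(tibble::tibble(mu = -1, sigma2 = 0.01))
  expect_true(neg$clipped_E)
  expect_equal(neg$lam_E, 0)
  expect_error(moments_to_rates(tibble::tibble(mu = 0, sigma2 = 1), a_E = 0),
               "positive")
})

test_that("rate -> moment -> rate roundtrips at machine precision", {
  set.seed(101)
  for (i in 1:20) {
    rates <- tibble::tibble(lam_E = runif(5, 0, 20), lam_I = runif(5, 0, 20))
    a_E <- runif(1, 0.05, 0.2)
    a_I <- runif(1, 0.05, 0.2)
    back <- moments_to_rates(rates_to_moments(rates, a_E, a_I), a_E, a_I)
    expect_equal(back$lam_E, rates$lam_E, tolerance = 1e-12)
    expect_equal(back$lam_I, rates$lam_I, tolerance = 1e-12)
    expect_false(any(back$clipped_E | back$clipped_I))
  }
})

test_that("noise-free simulation follows the deterministic relaxation", {
  # no drift, no noise: stays at the resting potential
  tr <- simulate_ou_ahp(100, dt = 0.1, mu = 0, sigma2 = 0)
  expect_equal(tr$v, rep(-65.5, 100), tolerance = 1e-12)
  # constant drift: exponential relaxation to u0 + mu * tau_m
  tr2 <- simulate_ou_ahp(5000, dt = 0.05, mu = 0.12, sigma2 = 0,
                         tau_m = 26, u0 = -65.5)
  expected <- -62.38 + (-65.5 + 62.38) * exp(-tr2$time / 26)
  expect_equal(tr2$v, expected, tolerance = 2e-3)
  # one spike at t = 0 with zero input: V = u0 + h(t)
  k <- make_test_kernel()
  tr3 <- simulate_ou_ahp(500, dt = 0.9, mu = 0, sigma2 = 0, kernel = k,
                         spikes = 0)
  expect_equal(tr3$v, -65.5 + synrates:::eval_ahp(k, tr3$time),
               tolerance = 1e-12)
})

test_that("long-run simulated moments match the stationary formulas", {
  tr <- simulate_ou_ahp(1e6, dt = 0.1, mu = 0.12, sigma2 = 0.16,
                        tau_m = 26, u0 = -65.5, seed = 7)
  u <- tr$u[tr$time > 500]  # discard the transient
  n_eff <- length(u) * 0.1 / (2 * 26)
  se_mean <- sqrt(2.08 / n_eff)
  se_var <- 2.08 * sqrt(2 / n_eff)
  expect_lt(abs(mean(u) - (-62.38)), 3 * se_mean)
  expect_lt(abs(var(u) - 2.08), 3 * se_var)
})

test_that("simulated autocorrelation decays with the membrane time constant", {
  tr <- simulate_ou_ahp(5e5, dt = 0.9, mu = 0, sigma2 = 0.16, tau_m = 26,
                        seed = 11)
  est <- estimate_tau_m(tibble::tibble(time = tr$time, v = tr$u, valid = TRUE))
  expect_lt(abs(est - 26) / 26, 0.05)
})

test_that("simulation is bit-reproducible under a fixed seed", {
  a <- simulate_ou_ahp(1000, dt = 0.1, mu = 0.1, sigma2 = 0.2, seed = 42)
  b <- simulate_ou_ahp(1000, dt = 0.1, mu = 0.1, sigma2 = 0.2, seed = 42)
  expect_bitwise_equal(a, b)
})

test_that("predictive band has the stated centre, width and coverage", {
  pb <- predictive_band(c(0, 10), tau_m = 26, u0 = -65.5, mu = 0,
                        sigma2 = 0.16)
  expect_equal(pb$mean, c(-65.5, -65.5))
  expect_equal(pb$upper - pb$mean, rep(1.96 * sqrt(2.08), 2))
  pb2 <- predictive_band(0, tau_m = 26, u0 = -65.5, mu = 0.12, sigma2 = 0.16)
  expect_equal(pb2$mean, -62.38)
  expect_equal(pb2$upper, -62.38 + 1.96 * sqrt(2.08), tolerance = 1e-6)
  # empirical coverage on a long stationary path
  tr <- simulate_ou_ahp(2e5, dt = 0.9, mu = 0.12, sigma2 = 0.16, tau_m = 26,
                        seed = 12, U0 = -62.38)
  band <- predictive_band(tr$time, tau_m = 26, u0 = -65.5, mu = 0.12,
                          sigma2 = 0.16)
  inside <- mean(tr$u > band$lower & tr$u < band$upper)
  expect_lt(abs(inside - 0.95), 0.01)
})
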