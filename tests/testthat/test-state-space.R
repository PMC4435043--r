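test_that("observation building follows the discretized dynamics", {
  time <- seq(0, 90, by = 0.9)
  # potential pinned at u0: all observations vanish
  m <- tibble::tibble(time = time, v = rep(-65.5, length(time)), valid = TRUE)
  obs <- build_observations(m, tau_m = 26, u0 = -65.5)
  expect_true(all(obs$z == 0))
  expect_true(all(obs$valid))
  # pure drift with no leak: Z_j = c * dt
  c_drift <- 0.25
  m2 <- tibble::tibble(time = time, v = -65.5 + c_drift * time, valid = TRUE)
  obs2 <- build_observations(m2, tau_m = Inf, u0 = -65.5)
  expect_equal(obs2$z, rep(c_drift * 0.9, nrow(obs2)), tolerance = 1e-9)
  # steps spanning a blank are flagged invalid
  time3 <- c(seq(0, 45, by = 0.9), seq(49.5, 90, by = 0.9))
  m3 <- tibble::tibble(time = time3, v = rnorm(length(time3), -65), valid = TRUE)
  obs3 <- build_observations(m3, 26, -65.5)
  expect_equal(sum(!obs3$valid), 1)
  expect_error(build_observations(m[1:5, ], 26, -65.5), "samples")
})

test_that("observations moment-match the generating input statistics", {
  tr <- simulate_ou_ahp(30000, dt = 0.9, mu = 0.12, sigma2 = 0.16,
                        tau_m = 26, seed = 14)
  obs <- build_observations(
    tibble::tibble(time = tr$time, v = tr$u, valid = TRUE), 26, -65.5)
  m_mom <- sum(obs$z) / sum(obs$dt)
  v_mom <- mean((obs$z - m_mom * obs$dt)^2 / obs$dt)
  expect_lt(abs(m_mom - 0.12), 3 * sqrt(0.16 / 0.9 / nrow(obs)))
  expect_lt(abs(v_mom - 0.16), 3 * 0.16 * sqrt(2 / nrow(obs)))
})

test_that("zero hyperparameters reduce to the static estimator", {
  tr <- simulate_ou_ahp(5000, dt = 0.9, mu = 0.12, sigma2 = 0.16,
                        tau_m = 26, seed = 15)
  obs <- build_observations(
    tibble::tibble(time = tr$time, v = tr$u, valid = TRUE), 26, -65.5)
  fs <- filter_smooth(obs, hyperparams(0, 0))
  m_static <- sum(obs$z) / sum(obs$dt)
  s_static <- log(mean((obs$z - m_static * obs$dt)^2 / obs$dt))
  se_m <- sqrt(0.16 / sum(obs$dt))
  # the smoothed path is flat and sits at the static estimates
  expect_lt(diff(range(fs$m_hat)), 1e-6)
  expect_lt(abs(fs$m_hat[1] - m_static), 2 * se_m)
  expect_lt(abs(fs$s_hat[1] - s_static), 2 * sqrt(2 / nrow(obs)))
})

test_that("with the variance state frozen the smoother is the Kalman smoother", {
  set.seed(16)
  K <- 300
  dt <- rep(0.9, K)
  gamma <- 0.012
  s_fix <- log(0.16)
  M <- cumsum(c(0.1, gamma * sqrt(dt[-1]) * rnorm(K - 1)))
  z <- M * dt + sqrt(exp(s_fix) * dt) * rnorm(K)
  obs <- tibble::tibble(time = cumsum(dt) - dt[1], z = z, dt = dt, valid = TRUE)
  init <- list(mean = c(0.1, s_fix), var = c(0.04, 0))
  fs <- filter_smooth(obs, hyperparams(gamma, 0), init = init)
  ref <- kalman_smooth_1d(z, dt, gamma, s_fix, m0 = 0.1, v0 = 0.04)
  expect_equal(fs$m_hat, ref$ms, tolerance = 1e-8)
  expect_equal(fs$m_var, ref$vs, tolerance = 1e-8)
  expect_equal(fs$m_filt, ref$mf, tolerance = 1e-8)
  expect_true(all(abs(fs$s_hat - s_fix) < 1e-6))
})

test_that("smoothing never inflates the filtered variance", {
  tr <- simulate_ou_ahp(3000, dt = 0.9, mu = 0.1, sigma2 = 0.2, seed = 17)
  obs <- build_observations(
    tibble::tibble(time = tr$time, v = tr$u, valid = TRUE), 26, -65.5)
  fs <- filter_smooth(obs, hyperparams(0.01, 0.005))
  expect_true(all(fs$m_var <= fs$m_filt_var + 1e-12))
  expect_true(all(fs$s_var <= fs$s_filt_var + 1e-12))
})

test_that("spike gaps propagate the prior without an update", {
  tr <- simulate_ou_ahp(2000, dt = 0.9, mu = 0.1, sigma2 = 0.16, seed = 18)
  m <- tibble::tibble(time = tr$time, v = tr$u, valid = TRUE)
  m <- m[-(500:504), ]  # carve a 4.5 ms hole
  obs <- build_observations(m, 26, -65.5)
  gap <- which(!obs$valid)
  expect_length(gap, 1)
  fs <- filter_smooth(obs, hyperparams(0.01, 0.005))
  # the filtered variance grows across the gap (prediction only)
  expect_gt(fs$m_filt_var[gap], fs$m_filt_var[gap - 1])
})

test_that("EM shrinks, recovers, or saturates the hyperparameters", {
  # static input: both scales collapse toward zero
  tr <- simulate_ou_ahp(5000, dt = 0.9, mu = 0.12, sigma2 = 0.16, seed = 3)
  obs <- build_observations(
    tibble::tibble(time = tr$time, v = tr$u, valid = TRUE), 26, -65.5)
  hp <- em_hyperparameters(obs)
  expect_lt(hp$gamma_M, 0.1 * 0.02)
  expect_lt(hp$gamma_S, 0.1 * 0.01)

  # drifting input of known scale: recovered within a factor of two
  set.seed(42)
  n <- 10000
  M <- cumsum(c(0.1, 0.015 * sqrt(0.9) * rnorm(n - 1)))
  tr2 <- simulate_ou_ahp(n, dt = 0.9, mu = M, sigma2 = 0.16, tau_m = 26,
                         seed = 5)
  obs2 <- build_observations(
    tibble::tibble(time = tr2$time, v = tr2$u, valid = TRUE), 26, -65.5)
  hp2 <- em_hyperparameters(obs2)
  expect_gt(hp2$gamma_M, 0.015 / 2)
  expect_lt(hp2$gamma_M, 0.015 * 2)

  # violently varying input: the cap is returned exactly
  set.seed(43)
  M3 <- cumsum(c(0.1, 0.1 * sqrt(0.9) * rnorm(5000 - 1)))
  tr3 <- simulate_ou_ahp(5000, dt = 0.9, mu = M3, sigma2 = 0.16, tau_m = 26,
                         seed = 6)
  obs3 <- build_observations(
    tibble::tibble(time = tr3$time, v = tr3$u, valid = TRUE), 26, -65.5)
  hp3 <- em_hyperparameters(obs3)
  expect_identical(hp3$gamma_M, 0.02)
})

test_that("EM log-likelihood is monotone within tolerance", {
  tr <- simulate_ou_ahp(4000, dt = 0.9, mu = 0.1, sigma2 = 0.16, seed = 44)
  obs <- build_observations(
    tibble::tibble(time = tr$time, v = tr$u, valid = TRUE), 26, -65.5)
  hp <- em_hyperparameters(obs)
  ll <- hp$trace$loglik
  expect_true(all(diff(ll) > -0.05))
})

test_that("a tracking smoother follows a mid-series step in the drift", {
  set.seed(19)
  n <- 6000
  dt <- 0.9
  M <- rep(c(0.05, 0.25), each = n / 2)
  tr <- simulate_ou_ahp(n, dt = dt, mu = M, sigma2 = 0.16, tau_m = 26,
                        seed = 20)
  obs <- build_observations(
    tibble::tibble(time = tr$time, v = tr$u, valid = TRUE), 26, -65.5)
  fs <- filter_smooth(obs, hyperparams(0.02, 0.005))
  half <- floor(nrow(obs) / 2)
  m1 <- mean(fs$m_hat[1:half])
  m2 <- mean(fs$m_hat[(half + 1):nrow(obs)])
  expect_lt(abs(m1 - 0.05), 0.1 * (0.25 - 0.05) + 0.02)
  expect_lt(abs(m2 - 0.25), 0.1 * (0.25 - 0.05) + 0.02)
})

test_that("constant input statistics are recovered from 15 s of data", {
  tr <- simulate_ou_ahp(16667, dt = 0.9, mu = 0.12, sigma2 = 0.16,
                        tau_m = 26, u0 = -65.5, seed = 22)
  obs <- build_observations(
    tibble::tibble(time = tr$time, v = tr$u, valid = TRUE), 26, -65.5)
  hp <- em_hyperparameters(obs)
  fs <- filter_smooth(obs, hp)
  expect_lt(abs(mean(fs$m_hat) - 0.12), 0.02)
  expect_lt(abs(mean(fs$sigma2_hat) - 0.16), 0.03)
})

test_that("estimates are direction-symmetric on stationary data", {
  tr <- simulate_ou_ahp(8000, dt = 0.9, mu = 0.12, sigma2 = 0.16,
                        tau_m = 26, seed = 23)
  fwd <- tibble::tibble(time = tr$time, v = tr$u, valid = TRUE)
  rev <- tibble::tibble(time = tr$time, v = rev(tr$u), valid = TRUE)
  hp <- hyperparams(0.005, 0.003)
  f1 <- filter_smooth(build_observations(fwd, 26, -65.5), hp)
  f2 <- filter_smooth(build_observations(rev, 26, -65.5), hp)
  # a reversed OU path is another realization of the same process; the
  # time-averaged estimates must agree within sampling error
  expect_lt(abs(mean(f1$m_hat) - mean(f2$m_hat)), 0.03)
  expect_lt(abs(mean(f1$s_hat) - mean(f2$s_hat)), 0.15)
})
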