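# noiseless trace on the analysis grid: V = base + h(t - t_f) with spikes
# far enough apart that lags beyond the kernel support identify u_inf
make_ahp_trace <- function(kernel, spikes = c(100, 1200), t_max = 2400,
                           base = -65, dt = 0.9) {
  time <- seq(0, t_max, by = dt)
  # align spikes to the grid so sampled lags are multiples of dt
  spikes <- time[vapply(spikes, function(s) which.min(abs(time - s)), 1L)]
  v <- base + synrates:::eval_ahp(kernel, synrates:::lag_since_spike(time, spikes))
  list(masked = tibble::tibble(time = time, v = v, valid = TRUE),
       spikes = spikes)
}

test_that("the least-squares kernel is exact on noiseless spike-aligned data", {
  k_true <- make_test_kernel()
  d <- make_ahp_trace(k_true)
  fit <- extract_ahp(d$masked, d$spikes)
  expect_equal(fit$u_inf, -65, tolerance = 1e-9)
  # recovered values equal the true kernel at every lag that was sampled
  lags <- synrates:::lag_since_spike(d$masked$time, d$spikes)
  lags <- unique(lags[lags <= 500])
  got <- synrates:::eval_ahp(fit$kernel, lags)
  expect_equal(got, synrates:::eval_ahp(k_true, lags), tolerance = 1e-9)
})

test_that("a silent kernel extracts as zero and u_inf as the trace mean", {
  time <- seq(0, 2000, by = 0.9)
  m <- tibble::tibble(time = time, v = rep(-63, length(time)), valid = TRUE)
  fit <- extract_ahp(m, spikes = 100)
  expect_equal(fit$u_inf, -63)
  expect_true(all(abs(fit$kernel$table$h) < 1e-12))
})

test_that("u_inf is unidentifiable without samples beyond the support", {
  time <- seq(0, 400, by = 0.9)
  m <- tibble::tibble(time = time, v = rep(-63, length(time)), valid = TRUE)
  expect_error(extract_ahp(m, spikes = 0), "support")
})

test_that("per-bin means minimize the squared error among binned kernels", {
  set.seed(8)
  k_true <- make_test_kernel()
  d <- make_ahp_trace(k_true)
  d$masked$v <- d$masked$v + rnorm(nrow(d$masked), 0, 0.5)
  fit <- extract_ahp(d$masked, d$spikes)
  lags <- synrates:::lag_since_spike(d$masked$time, d$spikes)
  sse <- function(kern, u_inf) {
    pred <- u_inf + synrates:::eval_ahp(kern, lags)
    sum((d$masked$v - pred)^2)
  }
  base <- sse(fit$kernel, fit$u_inf)
  for (b in c(1, 50, 200)) {
    for (delta in c(-0.2, 0.2)) {
      pert <- fit$kernel
      pert$table$h[b] <- pert$table$h[b] + delta
      expect_gt(sse(pert, fit$u_inf), base)
    }
  }
})

test_that("kernel extraction converges on stochastic traces", {
  k_true <- make_test_kernel()
  spikes <- seq(99.9, 449900, by = 900)  # grid-aligned, ~500 spikes
  tr <- simulate_ou_ahp(500000, dt = 0.9, mu = 0, sigma2 = 0.16, tau_m = 26,
                        u0 = -65, kernel = k_true, spikes = spikes, seed = 21)
  m <- tibble::tibble(time = tr$time, v = tr$v, valid = TRUE)
  fit <- extract_ahp(m, spikes)
  common <- fit$kernel$table$lag
  err <- synrates:::eval_ahp(fit$kernel, common) -
    synrates:::eval_ahp(k_true, common)
  expect_lt(max(abs(err)), 0.3)
})

test_that("double-exponential fit recovers generating parameters within 1%", {
  k <- make_test_kernel(a1 = 160, tau1 = 0.9, a2 = -12, tau2 = 37)
  fit <- fit_double_exp(k)
  expect_equal(fit$a1, 160, tolerance = 0.01)
  expect_equal(fit$tau1, 0.9, tolerance = 0.01)
  expect_equal(fit$a2, -12, tolerance = 0.01)
  expect_equal(fit$tau2, 37, tolerance = 0.01)
  expect_lt(fit$rss, 1e-6)
  td <- generics::tidy(fit)
  expect_equal(td$estimate, c(fit$a1, fit$tau1, fit$a2, fit$tau2))
})

test_that("degenerate kernels fit gracefully", {
  lags0 <- seq(0, 500, by = 0.9)
  k0 <- ahp_kernel(lags0, rep(0, length(lags0)))
  f0 <- fit_double_exp(k0)
  expect_equal(f0$a1, 0)
  expect_equal(f0$a2, 0)
  expect_equal(f0$rss, 0)
  # single exponential: second amplitude vanishes, fit is near-perfect
  lags <- seq(0, 500, by = 0.9)
  k1 <- ahp_kernel(lags, -8 * exp(-lags / 30))
  f1 <- fit_double_exp(k1)
  expect_lt(f1$rss, 1e-8)
})

test_that("subtracting the kernel inverts adding it", {
  k <- make_test_kernel()
  d <- make_ahp_trace(k)
  u <- subtract_ahp(d$masked, d$spikes, k)
  expect_equal(u$v, rep(-65, nrow(u)), tolerance = 1e-12)
  # zero kernel: identity
  u2 <- subtract_ahp(d$masked, d$spikes, NULL)
  expect_equal(u2$v, d$masked$v)
  # roundtrip against the simulator's kernel addition is exact
  spikes <- c(50, 700)
  tr <- simulate_ou_ahp(2000, dt = 0.9, mu = 0.1, sigma2 = 0.16, kernel = k,
                        spikes = spikes, seed = 31)
  m <- tibble::tibble(time = tr$time, v = tr$v, valid = TRUE)
  u3 <- subtract_ahp(m, spikes, k)
  expect_equal(u3$v, tr$u, tolerance = 1e-12)
})

test_that("kernels survive a text round-trip", {
  k <- make_test_kernel()
  path <- withr::local_tempfile(fileext = ".txt")
  write_ahp_kernel(k, path)
  k2 <- read_ahp_kernel(path)
  expect_equal(k2$support, k$support)
  expect_equal(k2$table$lag, k$table$lag)
  expect_equal(k2$table$h, k$table$h, tolerance = 1e-6)
})
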