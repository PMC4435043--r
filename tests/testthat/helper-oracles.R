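# Independent reference implementations used as oracles.  These are coded
# from the textbook formulas, separately from the package internals.

# Scalar Kalman filter + RTS smoother for the drift M alone, with known
# observation variance exp(s_fix) * dt per step:
#   M_{j+1} = M_j + N(0, gamma^2 dt_j),  z_j ~ N(M_j dt_j, exp(s_fix) dt_j)
kalman_smooth_1d <- function(z, dt, gamma, s_fix, m0, v0) {
  K <- length(z)
  mf <- vf <- mp <- vp <- numeric(K)
  m <- m0
  v <- v0
  for (j in seq_len(K)) {
    if (j > 1) v <- v + gamma^2 * dt[j - 1]
    mp[j] <- m; vp[j] <- v
    H <- dt[j]
    R <- exp(s_fix) * dt[j]
    Kg <- v * H / (H * v * H + R)
    m <- m + Kg * (z[j] - H * m)
    v <- (1 - Kg * H) * v
    mf[j] <- m; vf[j] <- v
  }
  ms <- mf; vs <- vf
  for (j in (K - 1):1) {
    G <- vf[j] / vp[j + 1]
    ms[j] <- mf[j] + G * (ms[j + 1] - mp[j + 1])
    vs[j] <- vf[j] + G^2 * (vs[j + 1] - vp[j + 1])
  }
  list(mf = mf, vf = vf, ms = ms, vs = vs)
}

# Naive quadratic-time spike scan: first sample above threshold after being
# below it, onset walked back to the earliest steep-slope sample in window.
brute_force_spikes <- function(time, v, thr = -30, slope_thr = 10,
                               back_ms = 3) {
  dt <- time[2] - time[1]
  onsets <- numeric(0)
  for (i in 2:length(v)) {
    if (v[i] >= thr && v[i - 1] < thr) {
      onset_i <- i
      for (k in seq(max(1, i - round(back_ms / dt)), i)) {
        if (k < length(v) && (v[k + 1] - v[k]) / dt > slope_thr) {
          onset_i <- k
          break
        }
      }
      onsets <- c(onsets, time[onset_i])
    }
  }
  onsets
}

# A smooth double-exponential afterhyperpolarization shape used as ground
# truth in kernel tests (values from a realistic fitted shape).
make_test_kernel <- function(bin = 0.9, support = 500,
                             a1 = 160, tau1 = 0.9, a2 = -12, tau2 = 37) {
  lags <- seq(0, support, by = bin)
  ahp_kernel(lags, a1 * exp(-lags / tau1) + a2 * exp(-lags / tau2),
             support = support)
}

expect_bitwise_equal <- function(a, b) expect_identical(a, b)
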