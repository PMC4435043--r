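#' Build the observation series for the state-space estimator
#'
#' Discretizing the leaky-integrator dynamics of the potential gives, for
#' each pair of consecutive samples,
#' `Z_j = U_{j+1} - U_j + (Delta_j / tau_m) * (U_j - u0)`,
#' which under the model is Gaussian with mean `M_j * Delta_j` and variance
#' `exp(S_j) * Delta_j`.  Steps spanning a spike blank (sampling gaps wider
#' than `gap_factor` times the median interval) carry no observation: they
#' are flagged invalid and only propagate the random-walk prior.
#'
#' @param masked A masked trace of the potential `U` on the analysis grid
#'   (tibble with `time`, `v`, `valid`).
#' @param tau_m Membrane time constant (ms), fixed upstream.
#' @param u0 Resting potential (mV), fixed upstream.
#' @param gap_factor Multiplier of the median sampling interval beyond
#'   which a step is treated as a gap.
#'
#' @return A tibble with columns `time` (interval start, ms), `z` (mV),
#'   `dt` (ms) and `valid`.
#' @export
build_observations <- function(masked, tau_m = 26, u0 = -65.5, gap_factor = 1.5) {
  stopifnot(tau_m > 0)
  masked <- as_masked(masked)
  t <- masked$time[masked$valid]
  u <- masked$v[masked$valid]
  if (length(u) < 11) stop("Need at least 11 valid samples.", call. = FALSE)
  dt <- diff(t)
  z <- diff(u) + (dt / tau_m) * (u[-length(u)] - u0)
  valid <- dt <= gap_factor * stats::median(dt)
  if (sum(valid) < 10) stop("Fewer than 10 valid observations.", call. = FALSE)
  tibble::tibble(time = t[-length(t)], z = z, dt = dt, valid = valid)
}

#' Random-walk hyperparameters
#'
#' Scales of the Gaussian random-walk priors on the input mean `M` and the
#' log input variance `S`.  Large values risk over-fitting the estimates to
#' noise, so both are capped (defaults 0.02 and 0.01).
#'
#' @param gamma_M Random-walk scale of `M` (mV/ms per sqrt(ms)).
#' @param gamma_S Random-walk scale of `S` (per sqrt(ms)).
#' @param caps Upper bounds for `c(gamma_M, gamma_S)`.
#' @return A list of class `hyperparams`.
#' @export
hyperparams <- function(gamma_M = 0.01, gamma_S = 0.005, caps = c(0.02, 0.01)) {
  stopifnot(gamma_M >= 0, gamma_S >= 0, length(caps) == 2)
  if (gamma_M > caps[1] || gamma_S > caps[2]) {
    stop("Hyperparameters exceed their caps.", call. = FALSE)
  }
  structure(list(gamma_M = gamma_M, gamma_S = gamma_S, caps = caps),
            class = "hyperparams")
}

#' @export
print.hyperparams <- function(x, ...) {
  cat(sprintf("<hyperparams> gamma_M = %.5g, gamma_S = %.5g (caps %.3g, %.3g)\n",
              x$gamma_M, x$gamma_S, x$caps[1], x$caps[2]))
  invisible(x)
}

# Default initial prior for (M, S): static maximum-likelihood drift and a
# method-of-moments log variance, with variances set to 10 times the
# per-step random-walk variance at the hyperparameter caps -- weakly
# informative around the static estimates, forgotten within a few steps.
default_init <- function(obs, caps = c(0.02, 0.01)) {
  z <- obs$z[obs$valid]
  dt <- obs$dt[obs$valid]
  m0 <- sum(z) / sum(dt)
  resid2 <- (z - m0 * dt)^2 / dt
  s0 <- log(max(mean(resid2), 1e-8))
  step <- stats::median(obs$dt)
  list(mean = c(m0, s0),
       var = c(10 * caps[1]^2 * step, 10 * caps[2]^2 * step))
}

# Gauss-Hermite nodes and weights (probabilists' convention: quadrature
# against the standard normal density) via Golub-Welsch.
gauss_hermite <- function(n) {
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1))
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = e$vectors[1, ]^2)
}

# Precomputed 9x9 tensor grid of 2-D unit nodes and log-weights.
gh_grid <- local({
  gh <- gauss_hermite(9)
  g <- expand.grid(i = seq_len(9), j = seq_len(9))
  list(u1 = gh$nodes[g$i], u2 = gh$nodes[g$j],
       lw = log(gh$weights[g$i]) + log(gh$weights[g$j]))
})

# Moment-matched Gaussian update of a single step: prior N(m, P) times the
# observation density N(zz; M d, e^S d).  A Newton (Laplace) fit locates
# the posterior, then Gauss-Hermite quadrature centred on the Laplace
# Gaussian matches the exact posterior mean and covariance (removing the
# mode-versus-mean bias of the skewed log-variance posterior) and yields
# the step's marginal likelihood.  Covariances are (p11, p12, p22).
gh_update <- function(m1, m2, p11, p12, p22, zz, d,
                      max_newton = 30, tol = 1e-10) {
  log2pi <- log(2 * pi)
  det_p <- p11 * p22 - p12 * p12
  if (det_p <= 0) {  # jitter-and-retry
    p11 <- p11 + 1e-10; p22 <- p22 + 1e-10
    det_p <- p11 * p22 - p12 * p12
    if (det_p <= 0) stop("Non-positive-definite covariance in update.")
  }
  i11 <- p22 / det_p; i12 <- -p12 / det_p; i22 <- p11 / det_p
  x1 <- m1; x2 <- m2
  obj <- function(x1, x2) {
    r <- zz - x1 * d
    e1 <- x1 - m1; e2 <- x2 - m2
    -0.5 * (r * r * exp(-x2) / d + x2 + log(d) + log2pi) -
      0.5 * (e1 * e1 * i11 + 2 * e1 * e2 * i12 + e2 * e2 * i22)
  }
  f0 <- obj(x1, x2)
  for (it in seq_len(max_newton)) {
    r <- zz - x1 * d
    es <- exp(-x2)
    gl1 <- r * es
    gl2 <- 0.5 * r * r * es / d - 0.5
    h11 <- d * es                # negative Hessian of the log-likelihood
    h22 <- 0.5 * r * r * es / d
    h12 <- r * es
    e1 <- x1 - m1; e2 <- x2 - m2
    g1 <- gl1 - (i11 * e1 + i12 * e2)
    g2 <- gl2 - (i12 * e1 + i22 * e2)
    a11 <- h11 + i11; a12 <- h12 + i12; a22 <- h22 + i22
    det_a <- a11 * a22 - a12 * a12
    if (det_a <= 1e-12 || a11 <= 0) {  # enforce positive definiteness
      bump <- abs(a12) + 1e-8
      a11 <- a11 + bump; a22 <- a22 + bump
      det_a <- a11 * a22 - a12 * a12
    }
    d1 <- (a22 * g1 - a12 * g2) / det_a
    d2 <- (a11 * g2 - a12 * g1) / det_a
    step <- 1
    repeat {
      f1 <- obj(x1 + step * d1, x2 + step * d2)
      if (f1 >= f0 - 1e-12 || step < 1e-4) break
      step <- step / 2
    }
    x1 <- x1 + step * d1; x2 <- x2 + step * d2
    moved <- abs(step * d1) + abs(step * d2)
    f0 <- max(f0, f1)
    if (moved < tol) break
  }
  # curvature at the mode -> Laplace covariance
  r <- zz - x1 * d
  es <- exp(-x2)
  h11 <- d * es; h22 <- 0.5 * r * r * es / d; h12 <- r * es
  a11 <- h11 + i11; a12 <- h12 + i12; a22 <- h22 + i22
  det_a <- a11 * a22 - a12 * a12
  if (det_a <= 1e-12 || a11 <= 0) {
    bump <- abs(a12) + 1e-8
    a11 <- a11 + bump; a22 <- a22 + bump
    det_a <- a11 * a22 - a12 * a12
  }
  p11n <- a22 / det_a; p12n <- -a12 / det_a; p22n <- a11 / det_a
  # Gauss-Hermite moment matching centred on the Laplace Gaussian
  L11 <- sqrt(p11n)
  L21 <- p12n / L11
  L22 <- sqrt(max(p22n - L21 * L21, 1e-14))
  xs1 <- x1 + L11 * gh_grid$u1
  xs2 <- x2 + L21 * gh_grid$u1 + L22 * gh_grid$u2
  rk <- zz - xs1 * d
  llik_k <- -0.5 * (rk * rk * exp(-xs2) / d + xs2 + log(d) + log2pi)
  e1 <- xs1 - m1; e2 <- xs2 - m2
  lprior_k <- -0.5 * (e1 * e1 * i11 + 2 * e1 * e2 * i12 + e2 * e2 * i22) -
    log2pi - 0.5 * log(det_p)
  lq_k <- -0.5 * (gh_grid$u1^2 + gh_grid$u2^2) - log2pi - log(L11 * L22)
  lw <- gh_grid$lw + llik_k + lprior_k - lq_k
  lmax <- max(lw)
  w <- exp(lw - lmax)
  zc <- sum(w)
  logz <- lmax + log(zc)
  w <- w / zc
  n1 <- sum(w * xs1); n2 <- sum(w * xs2)
  d1 <- xs1 - n1; d2 <- xs2 - n2
  q11 <- sum(w * d1 * d1); q12 <- sum(w * d1 * d2); q22 <- sum(w * d2 * d2)
  if (q11 * q22 - q12 * q12 <= 0 || q11 <= 0) {  # fall back to Laplace
    n1 <- x1; n2 <- x2
    q11 <- p11n; q12 <- p12n; q22 <- p22n
  }
  list(m1 = n1, m2 = n2, p11 = q11, p12 = q12, p22 = q22, logz = logz)
}

# Backward Rauch-Tung-Striebel pass (identity transition) over stored
# filtered/predicted Gaussians; also returns the lag-one smoothed
# cross-covariances Cov(x_{j+1}, x_j | all data) needed by the EM M-step.
rts_pass <- function(st) {
  K <- length(st$mf1)
  ms1 <- st$mf1; ms2 <- st$mf2
  ps11 <- st$pf11; ps12 <- st$pf12; ps22 <- st$pf22
  c11 <- c22 <- numeric(K)
  if (K >= 2) {
    for (j in (K - 1):1) {
      det_pp <- st$pp11[j + 1] * st$pp22[j + 1] - st$pp12[j + 1]^2
      ip11 <- st$pp22[j + 1] / det_pp; ip12 <- -st$pp12[j + 1] / det_pp
      ip22 <- st$pp11[j + 1] / det_pp
      # gain G = P_f P_pred^{-1}
      g11 <- st$pf11[j] * ip11 + st$pf12[j] * ip12
      g12 <- st$pf11[j] * ip12 + st$pf12[j] * ip22
      g21 <- st$pf12[j] * ip11 + st$pf22[j] * ip12
      g22 <- st$pf12[j] * ip12 + st$pf22[j] * ip22
      dm1 <- ms1[j + 1] - st$mp1[j + 1]
      dm2 <- ms2[j + 1] - st$mp2[j + 1]
      ms1[j] <- st$mf1[j] + g11 * dm1 + g12 * dm2
      ms2[j] <- st$mf2[j] + g21 * dm1 + g22 * dm2
      dp11 <- ps11[j + 1] - st$pp11[j + 1]
      dp12 <- ps12[j + 1] - st$pp12[j + 1]
      dp22 <- ps22[j + 1] - st$pp22[j + 1]
      # P_s[j] = P_f[j] + G dP G'
      t11 <- g11 * dp11 + g12 * dp12; t12 <- g11 * dp12 + g12 * dp22
      t21 <- g21 * dp11 + g22 * dp12; t22 <- g21 * dp12 + g22 * dp22
      ps11[j] <- st$pf11[j] + t11 * g11 + t12 * g12
      ps12[j] <- st$pf12[j] + t11 * g21 + t12 * g22
      ps22[j] <- st$pf22[j] + t21 * g21 + t22 * g22
      # lag-one: Cov(x_{j+1}, x_j) = P_s[j+1] G'
      c11[j] <- ps11[j + 1] * g11 + ps12[j + 1] * g12
      c22[j] <- ps12[j + 1] * g21 + ps22[j + 1] * g22
    }
  }
  c(st, list(ms1 = ms1, ms2 = ms2, ps11 = ps11, ps12 = ps12, ps22 = ps22,
             c11 = c11, c22 = c22))
}

# One forward-backward pass of the assumed-density Gaussian filter and
# smoother: per step, Gaussian predict with Q = diag(gM^2 dt, gS^2 dt) and
# a moment-matched measurement update (gh_update); invalid steps propagate
# the prior only.  Returns filtered, predicted and smoothed quantities
# plus the accumulated approximate marginal log-likelihood.
adf_pass <- function(z, dt, valid, gamma_M, gamma_S, init,
                     max_newton = 30, tol = 1e-10) {
  K <- length(z)
  mf1 <- mf2 <- pf11 <- pf12 <- pf22 <- numeric(K)
  mp1 <- mp2 <- pp11 <- pp12 <- pp22 <- numeric(K)
  loglik <- 0
  m1 <- init$mean[1]; m2 <- init$mean[2]
  p11 <- init$var[1]; p12 <- 0; p22 <- init$var[2]
  qm <- gamma_M^2; qs <- gamma_S^2
  for (j in seq_len(K)) {
    if (j > 1) {  # predict across the preceding interval
      p11 <- p11 + qm * dt[j - 1]
      p22 <- p22 + qs * dt[j - 1]
    }
    mp1[j] <- m1; mp2[j] <- m2
    pp11[j] <- p11; pp12[j] <- p12; pp22[j] <- p22
    if (valid[j]) {
      up <- gh_update(m1, m2, p11, p12, p22, z[j], dt[j], max_newton, tol)
      m1 <- up$m1; m2 <- up$m2
      p11 <- up$p11; p12 <- up$p12; p22 <- up$p22
      loglik <- loglik + up$logz
    }
    mf1[j] <- m1; mf2[j] <- m2
    pf11[j] <- p11; pf12[j] <- p12; pf22[j] <- p22
  }
  st <- list(mf1 = mf1, mf2 = mf2, pf11 = pf11, pf12 = pf12, pf22 = pf22,
             mp1 = mp1, mp2 = mp2, pp11 = pp11, pp12 = pp12, pp22 = pp22)
  out <- rts_pass(st)
  out$loglik <- loglik
  out
}

inv2 <- function(a11, a12, a22) {
  d <- a11 * a22 - a12 * a12
  list(i11 = a22 / d, i12 = -a12 / d, i22 = a11 / d, det = d)
}

# Forward-backward pass where each valid step carries a Gaussian likelihood
# site in natural parameters (precision lam11/lam12/lam22, shift eta1/eta2)
# instead of the exact observation density.
site_chain_pass <- function(dt, valid, gamma_M, gamma_S, init, sites) {
  K <- length(dt)
  mf1 <- mf2 <- pf11 <- pf12 <- pf22 <- numeric(K)
  mp1 <- mp2 <- pp11 <- pp12 <- pp22 <- numeric(K)
  m1 <- init$mean[1]; m2 <- init$mean[2]
  p11 <- init$var[1]; p12 <- 0; p22 <- init$var[2]
  qm <- gamma_M^2; qs <- gamma_S^2
  for (j in seq_len(K)) {
    if (j > 1) {
      p11 <- p11 + qm * dt[j - 1]
      p22 <- p22 + qs * dt[j - 1]
    }
    mp1[j] <- m1; mp2[j] <- m2
    pp11[j] <- p11; pp12[j] <- p12; pp22[j] <- p22
    if (valid[j]) {
      if (p11 * p22 - p12 * p12 <= 0) {  # jitter a degenerate prediction
        p11 <- p11 + 1e-10; p22 <- p22 + 1e-10
      }
      ip <- inv2(p11, p12, p22)
      j11 <- ip$i11 + sites$lam11[j]
      j12 <- ip$i12 + sites$lam12[j]
      j22 <- ip$i22 + sites$lam22[j]
      h1 <- ip$i11 * m1 + ip$i12 * m2 + sites$eta1[j]
      h2 <- ip$i12 * m1 + ip$i22 * m2 + sites$eta2[j]
      pj <- inv2(j11, j12, j22)
      if (is.finite(pj$det) && pj$det > 0 && j11 > 0) {
        p11 <- pj$i11; p12 <- pj$i12; p22 <- pj$i22
        m1 <- p11 * h1 + p12 * h2
        m2 <- p12 * h1 + p22 * h2
      }
    }
    mf1[j] <- m1; mf2[j] <- m2
    pf11[j] <- p11; pf12[j] <- p12; pf22[j] <- p22
  }
  rts_pass(list(mf1 = mf1, mf2 = mf2, pf11 = pf11, pf12 = pf12, pf22 = pf22,
                mp1 = mp1, mp2 = mp2, pp11 = pp11, pp12 = pp12, pp22 = pp22))
}

# Expectation-propagation refinement of the single-pass smoother.  The
# filter pass approximates each observation by the Gaussian site implied by
# its update against the *filtered* prior; here each site is re-derived by
# moment matching against its cavity under the current *smoothed*
# approximation, and the chain is re-smoothed, for a few sweeps.  This
# removes the residual bias of one-pass assumed-density smoothing for the
# skewed log-variance component.
ep_refine <- function(z, dt, valid, gamma_M, gamma_S, init, res0,
                      sweeps = 2, damping = 0.8) {
  K <- length(z)
  # initial sites from the filter pass: site = filtered - predicted naturals
  sites <- list(lam11 = numeric(K), lam12 = numeric(K), lam22 = numeric(K),
                eta1 = numeric(K), eta2 = numeric(K))
  for (j in which(valid)) {
    pin1 <- res0$pf11[j] < 1e-8 || res0$pp11[j] < 1e-8
    pin2 <- res0$pf22[j] < 1e-8 || res0$pp22[j] < 1e-8
    if (pin1 && pin2) next
    if (pin1 || pin2) {
      # a pinned component carries no usable site information; extract the
      # free component's site by the exact scalar formulas instead of a
      # catastrophically cancelling 2x2 inversion
      if (pin2) {
        sites$lam11[j] <- 1 / res0$pf11[j] - 1 / res0$pp11[j]
        sites$eta1[j] <- res0$mf1[j] / res0$pf11[j] - res0$mp1[j] / res0$pp11[j]
      } else {
        sites$lam22[j] <- 1 / res0$pf22[j] - 1 / res0$pp22[j]
        sites$eta2[j] <- res0$mf2[j] / res0$pf22[j] - res0$mp2[j] / res0$pp22[j]
      }
      next
    }
    ipf <- inv2(res0$pf11[j], res0$pf12[j], res0$pf22[j])
    ipp <- inv2(res0$pp11[j], res0$pp12[j], res0$pp22[j])
    sites$lam11[j] <- ipf$i11 - ipp$i11
    sites$lam12[j] <- ipf$i12 - ipp$i12
    sites$lam22[j] <- ipf$i22 - ipp$i22
    sites$eta1[j] <- (ipf$i11 * res0$mf1[j] + ipf$i12 * res0$mf2[j]) -
      (ipp$i11 * res0$mp1[j] + ipp$i12 * res0$mp2[j])
    sites$eta2[j] <- (ipf$i12 * res0$mf1[j] + ipf$i22 * res0$mf2[j]) -
      (ipp$i12 * res0$mp1[j] + ipp$i22 * res0$mp2[j])
  }
  cur <- res0
  for (sw in seq_len(sweeps)) {
    for (j in which(valid)) {
      isq <- inv2(cur$ps11[j], cur$ps12[j], cur$ps22[j])
      if (!is.finite(isq$det) || isq$det <= 0 ||
          !all(is.finite(c(isq$i11, isq$i12, isq$i22)))) next
      # a pinned component (marginal variance ~ 0) makes the cavity
      # subtraction catastrophically ill-conditioned; keep the filter site
      if (isq$i11 > 1e8 || isq$i22 > 1e8) next
      # cavity = smoothed marginal minus this site
      c11 <- isq$i11 - sites$lam11[j]
      c12 <- isq$i12 - sites$lam12[j]
      c22 <- isq$i22 - sites$lam22[j]
      cdet <- c11 * c22 - c12 * c12
      if (!is.finite(cdet) || cdet <= 0 || c11 <= 0) next
      ch1 <- (isq$i11 * cur$ms1[j] + isq$i12 * cur$ms2[j]) - sites$eta1[j]
      ch2 <- (isq$i12 * cur$ms1[j] + isq$i22 * cur$ms2[j]) - sites$eta2[j]
      cv <- inv2(c11, c12, c22)
      cm1 <- cv$i11 * ch1 + cv$i12 * ch2
      cm2 <- cv$i12 * ch1 + cv$i22 * ch2
      up <- gh_update(cm1, cm2, cv$i11, cv$i12, cv$i22, z[j], dt[j])
      it <- inv2(up$p11, up$p12, up$p22)
      if (it$det <= 0) next
      nl11 <- it$i11 - c11; nl12 <- it$i12 - c12; nl22 <- it$i22 - c22
      ne1 <- (it$i11 * up$m1 + it$i12 * up$m2) - ch1
      ne2 <- (it$i12 * up$m1 + it$i22 * up$m2) - ch2
      sites$lam11[j] <- (1 - damping) * sites$lam11[j] + damping * nl11
      sites$lam12[j] <- (1 - damping) * sites$lam12[j] + damping * nl12
      sites$lam22[j] <- (1 - damping) * sites$lam22[j] + damping * nl22
      sites$eta1[j] <- (1 - damping) * sites$eta1[j] + damping * ne1
      sites$eta2[j] <- (1 - damping) * sites$eta2[j] + damping * ne2
    }
    cur <- site_chain_pass(dt, valid, gamma_M, gamma_S, init, sites)
  }
  cur$loglik <- res0$loglik
  cur
}

#' Gaussian assumed-density filter and smoother for the input statistics
#'
#' Estimates the posterior of the latent input mean `M_j` and log input
#' variance `S_j` given the observation series, under independent Gaussian
#' random-walk priors.  The forward pass is an assumed-density filter: a
#' Gaussian predict step followed by a measurement update that locates the
#' per-step posterior by Newton iteration and then moment-matches it by
#' Gauss-Hermite quadrature (so posterior means, not modes, are tracked
#' despite the skewness induced by the log-variance state).  The backward
#' pass is Rauch-Tung-Striebel smoothing of the Gaussian sequence, followed
#' by `sweeps` expectation-propagation refinements in which each
#' observation's Gaussian site is re-matched against its cavity under the
#' smoothed approximation.  Invalid steps (spike-onset gaps) propagate the
#' prior without a measurement update.
#'
#' @param obs Observation series from [build_observations()].
#' @param hp A [hyperparams()] object (or list with `gamma_M`, `gamma_S`).
#' @param init Optional prior for the first state: list with `mean`
#'   (`c(M, S)`) and `var` (`c(var_M, var_S)`).  Defaults to a static
#'   moment-matched estimate with diffuse variances.
#' @param sweeps Number of expectation-propagation refinement sweeps after
#'   the initial forward-backward pass; 0 gives the plain one-pass
#'   smoother.
#'
#' @return A tibble with one row per step: `time`, smoothed posterior means
#'   and variances `m_hat`, `m_var`, `s_hat`, `s_var`, the implied input
#'   variance `sigma2_hat = exp(s_hat)`, and filtered quantities `m_filt`,
#'   `m_filt_var`, `s_filt`, `s_filt_var`.  The approximate marginal
#'   log-likelihood is attached as attribute `loglik`, the lag-one smoothed
#'   cross-covariances as attributes `cross_mm` and `cross_ss`.
#' @export
filter_smooth <- function(obs, hp = hyperparams(), init = NULL, sweeps = 2) {
  stopifnot(is.data.frame(obs), all(c("z", "dt", "valid") %in% names(obs)))
  if (is.null(init)) {
    caps <- if (inherits(hp, "hyperparams")) hp$caps else c(0.02, 0.01)
    init <- default_init(obs, caps)
  }
  res <- adf_pass(obs$z, obs$dt, obs$valid, hp$gamma_M, hp$gamma_S, init)
  if (sweeps > 0) {
    res <- ep_refine(obs$z, obs$dt, obs$valid, hp$gamma_M, hp$gamma_S, init,
                     res, sweeps = sweeps)
  }
  out <- tibble::tibble(
    time = obs$time,
    m_hat = res$ms1, m_var = res$ps11,
    s_hat = res$ms2, s_var = res$ps22,
    sigma2_hat = exp(res$ms2),
    m_filt = res$mf1, m_filt_var = res$pf11,
    s_filt = res$mf2, s_filt_var = res$pf22
  )
  attr(out, "loglik") <- res$loglik
  attr(out, "cross_mm") <- res$c11
  attr(out, "cross_ss") <- res$c22
  out
}

#' Select the random-walk hyperparameters by expectation-maximization
#'
#' Alternates smoothing (E-step) with the closed-form M-step
#' `gamma^2 = mean_j E[(X_{j+1} - X_j)^2] / Delta_j` for each component,
#' where the expectation uses the smoothed means, variances and lag-one
#' cross-covariances.  The result is clipped at the caps to guard against
#' over-fitting.
#'
#' @inheritParams filter_smooth
#' @param init_hp Starting [hyperparams()].
#' @param max_iter Maximum EM iterations.
#' @param tol Relative-change convergence tolerance on the hyperparameters.
#'
#' Because the EM map contracts very slowly when a random-walk variance
#' approaches zero (the static-input limit), each cycle applies Aitken
#' delta-squared extrapolation to the per-component variance updates,
#' guarded by the approximate marginal likelihood: if the extrapolated
#' point does not improve on the plain EM step it is discarded.
#'
#' @return A [hyperparams()] object with extra fields: `iterations` (number
#'   of E-steps), `converged`, and `trace` (tibble of per-iteration values
#'   and approximate log-likelihood).
#' @export
em_hyperparameters <- function(obs, init_hp = hyperparams(), max_iter = 50,
                               tol = 1e-4, init = NULL) {
  caps <- init_hp$caps
  caps2 <- caps^2
  if (is.null(init)) init <- default_init(obs, caps)
  dt <- obs$dt
  K <- length(dt)
  n_pass <- 0L
  trace <- list()
  # One EM step on the squared scales q = (gamma_M^2, gamma_S^2):
  # E-step smooths, M-step averages the expected squared state increments
  # per unit time; the result is clipped at the caps.
  em_step <- function(q) {
    res <- adf_pass(obs$z, dt, obs$valid, sqrt(q[1]), sqrt(q[2]), init)
    n_pass <<- n_pass + 1L
    dm2 <- (res$ms1[-1] - res$ms1[-K])^2 +
      res$ps11[-1] + res$ps11[-K] - 2 * res$c11[-K]
    ds2 <- (res$ms2[-1] - res$ms2[-K])^2 +
      res$ps22[-1] + res$ps22[-K] - 2 * res$c22[-K]
    q_new <- c(mean(pmax(dm2, 0) / dt[-K]), mean(pmax(ds2, 0) / dt[-K]))
    list(q = pmin(pmax(q_new, 0), caps2), loglik = res$loglik)
  }
  loglik_at <- function(q) {
    n_pass <<- n_pass + 1L
    adf_pass(obs$z, dt, obs$valid, sqrt(q[1]), sqrt(q[2]), init)$loglik
  }
  q <- c(init_hp$gamma_M, init_hp$gamma_S)^2
  converged <- FALSE
  ll_prev <- -Inf
  while (n_pass < max_iter) {
    q_old <- q
    s1 <- em_step(q)
    trace[[length(trace) + 1]] <- tibble::tibble(
      iter = n_pass, gamma_M = sqrt(s1$q[1]), gamma_S = sqrt(s1$q[2]),
      loglik = s1$loglik)
    if (n_pass >= max_iter) { q <- s1$q; break }
    s2 <- em_step(s1$q)
    r1 <- s1$q - q
    r2 <- s2$q - s1$q
    # Per component: if the EM increments contract geometrically, Aitken
    # extrapolation lands at the fixed point; if they do not contract the
    # optimum lies at or beyond the nearest boundary, so propose it.  The
    # likelihood guard below rejects bad proposals at the cost of one pass.
    q_acc <- s2$q
    for (cc in 1:2) {
      if (abs(r1[cc]) < 1e-14) next
      rho <- r2[cc] / r1[cc]
      q_acc[cc] <- if (rho < 1 - 1e-3 && rho > -1) {
        q[cc] + r1[cc] / (1 - rho)
      } else if (r2[cc] > 0) caps2[cc] else 0
    }
    q_acc <- pmin(pmax(q_acc, 0), caps2)
    q <- s2$q
    ll <- s2$loglik
    if (any(q_acc != s2$q) && n_pass < max_iter) {
      ll_acc <- loglik_at(q_acc)
      if (ll_acc >= s2$loglik - 1e-6) {
        q <- q_acc
        ll <- ll_acc
      }
    }
    trace[[length(trace) + 1]] <- tibble::tibble(
      iter = n_pass, gamma_M = sqrt(q[1]), gamma_S = sqrt(q[2]), loglik = ll)
    # stop on a stationary iterate or a flat likelihood: near the optimum
    # the profile is extremely flat in the hyperparameters, so chasing
    # further digits does not change the smoothed paths
    if (all(abs(sqrt(q) - sqrt(q_old)) < pmax(tol * sqrt(q_old), 1e-3 * caps)) ||
        (is.finite(ll_prev) && ll - ll_prev < 0.01)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
  }
  if (!converged) {
    warning("EM did not converge within `max_iter` smoothing passes; returning last iterate.",
            call. = FALSE)
  }
  out <- hyperparams(sqrt(q[1]), sqrt(q[2]), caps)
  out$iterations <- n_pass
  out$converged <- converged
  out$trace <- dplyr::bind_rows(trace)
  out
}
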