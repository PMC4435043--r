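#' Particle filter and backward-simulation smoother
#'
#' A bootstrap particle filter with systematic resampling, followed by a
#' backward-simulation smoother, for the same state-space model as
#' [filter_smooth()].  Because it makes no Gaussian approximation it
#' converges (in the number of particles) to the exact Bayesian posterior,
#' and serves as the reference oracle for the assumed-density smoother.
#'
#' @inheritParams filter_smooth
#' @param n_particles Number of filter particles (>= 1000).
#' @param n_draws Number of backward-simulated smoothing trajectories.
#' @param ess_frac Resampling is triggered when the effective sample size
#'   drops below this fraction of `n_particles`.
#' @param seed Optional integer seed.
#'
#' @return A tibble with columns `time`, `m_hat`, `m_var`, `s_hat`,
#'   `s_var`, `sigma2_hat` (smoothed) and `m_filt`, `s_filt`, `ess`
#'   (filtered).  A warning is raised if the effective sample size ever
#'   drops below 10.
#' @export
particle_smoother <- function(obs, hp = hyperparams(), n_particles = 2000,
                              n_draws = 2000, init = NULL, ess_frac = 0.5,
                              seed = NULL) {
  stopifnot(is.data.frame(obs), all(c("z", "dt", "valid") %in% names(obs)),
            n_particles >= 1000)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) {
    caps <- if (inherits(hp, "hyperparams")) hp$caps else c(0.02, 0.01)
    init <- default_init(obs, caps)
  }
  res <- particle_smoother_cpp(obs$z, obs$dt, obs$valid,
                               hp$gamma_M, hp$gamma_S,
                               init$mean[1], init$mean[2],
                               init$var[1], init$var[2],
                               as.integer(n_particles), as.integer(n_draws),
                               ess_frac)
  if (min(res$ess) < 10) {
    warning(sprintf("Severe particle degeneracy: min ESS = %.1f.", min(res$ess)),
            call. = FALSE)
  }
  tibble::tibble(
    time = obs$time,
    m_hat = res$m_hat, m_var = res$m_var,
    s_hat = res$s_hat, s_var = res$s_var,
    sigma2_hat = exp(res$s_hat),
    m_filt = res$m_filt, s_filt = res$s_filt,
    ess = res$ess
  )
}
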