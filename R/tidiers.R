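#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an estimation result into a per-time tibble
#'
#' @param x An [run_estimation()] result.
#' @param ... Unused.
#' @return A tibble with one row per analysis step: `time`, `mu`,
#'   `sigma2`, their posterior variances, `lam_E`, `lam_I` and clip flags.
#' @export
tidy.estimation_result <- function(x, ...) {
  tibble::tibble(
    time = x$stats$time,
    mu = x$stats$m_hat, mu_var = x$stats$m_var,
    sigma2 = x$stats$sigma2_hat, s_var = x$stats$s_var,
    lam_E = x$rates$lam_E, lam_I = x$rates$lam_I,
    clipped_E = x$rates$clipped_E, clipped_I = x$rates$clipped_I
  )
}

#' One-row summary of an estimation result
#'
#' @inheritParams tidy.estimation_result
#' @return A tibble with the fixed constants, EM-selected hyperparameters,
#'   time-averaged input statistics and rates, and bookkeeping counts.
#' @export
glance.estimation_result <- function(x, ...) {
  tibble::tibble(
    n_obs = nrow(x$obs), n_spikes = length(x$spikes),
    tau_m = x$tau_m, u0 = x$cfg$u0,
    gamma_M = x$hp$gamma_M, gamma_S = x$hp$gamma_S,
    em_iterations = x$hp$iterations, em_converged = x$hp$converged,
    mean_mu = mean(x$stats$m_hat),
    mean_sigma2 = mean(x$stats$sigma2_hat),
    mean_lam_E = mean(x$rates$lam_E),
    mean_lam_I = mean(x$rates$lam_I),
    frac_clipped = mean(x$rates$clipped_E | x$rates$clipped_I),
    loglik = attr(x$stats, "loglik")
  )
}

#' @export
tidy.ahp_double_exp <- function(x, ...) {
  tibble::tibble(term = c("a1", "tau1", "a2", "tau2"),
                 estimate = c(x$a1, x$tau1, x$a2, x$tau2),
                 unit = c("mV", "ms", "mV", "ms"))
}

#' @export
glance.ahp_double_exp <- function(x, ...) {
  tibble::tibble(rss = x$rss, converged = x$converged)
}

#' @export
tidy.ahp_kernel <- function(x, ...) x$table

#' @export
tidy.hyperparams <- function(x, ...) {
  tibble::tibble(term = c("gamma_M", "gamma_S"),
                 estimate = c(x$gamma_M, x$gamma_S),
                 cap = x$caps)
}
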