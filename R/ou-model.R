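#' Stationary mean and variance of the leaky membrane potential
#'
#' For constant input statistics the sub-threshold potential is an
#' Ornstein-Uhlenbeck process whose stationary distribution is Gaussian with
#' mean `mu0 * tau_m + u0` and variance `sigma2_0 * tau_m / 2`.
#'
#' @param mu0 Input mean (mV/ms).
#' @param sigma2_0 Input variance (mV^2/ms); must be positive.
#' @param tau_m Membrane time constant (ms); must be positive.
#' @param u0 Resting potential (mV).
#'
#' @return A tibble with one row and columns `mean` (mV) and `variance`
#'   (mV^2).
#' @examples
#' stationary_moments(0.12, 0.16, tau_m = 26, u0 = -65.5)
#' @export
stationary_moments <- function(mu0, sigma2_0, tau_m, u0) {
  if (any(tau_m <= 0)) stop("`tau_m` must be positive.", call. = FALSE)
  if (any(sigma2_0 <= 0)) stop("`sigma2_0` must be positive.", call. = FALSE)
  tibble::tibble(
    mean = mu0 * tau_m + u0,
    variance = sigma2_0 * tau_m / 2
  )
}

#' Convert synaptic input rates to input statistics
#'
#' The diffusion approximation of summed Poisson synaptic impulses gives the
#' drift and infinitesimal variance of the membrane potential as
#' `mu = a_E * lam_E - a_I * lam_I` and
#' `sigma2 = a_E^2 * lam_E + a_I^2 * lam_I`.
#'
#' @param rates A data frame with columns `lam_E` and `lam_I`, total
#'   excitatory and inhibitory presynaptic rates (kHz, i.e. events/ms).
#'   Negative rates are an error.
#' @param a_E,a_I Excitatory / inhibitory post-synaptic potential amplitudes
#'   at the soma (mV); both must be positive.
#'
#' @return The input tibble with columns `mu` (mV/ms) and `sigma2`
#'   (mV^2/ms) appended.
#' @examples
#' rates_to_moments(tibble::tibble(lam_E = 7.76, lam_I = 8.16))
#' @seealso [moments_to_rates()] for the inverse map.
#' @export
rates_to_moments <- function(rates, a_E = 0.11, a_I = 0.09) {
  check_psp(a_E, a_I)
  stopifnot(is.data.frame(rates), all(c("lam_E", "lam_I") %in% names(rates)))
  if (any(rates$lam_E < 0, na.rm = TRUE) || any(rates$lam_I < 0, na.rm = TRUE)) {
    stop("Input rates must be non-negative.", call. = FALSE)
  }
  dplyr::mutate(
    tibble::as_tibble(rates),
    mu = a_E * .data$lam_E - a_I * .data$lam_I,
    sigma2 = a_E^2 * .data$lam_E + a_I^2 * .data$lam_I
  )
}

#' Recover synaptic input rates from input statistics
#'
#' Inverts the diffusion-approximation moment equations for the total
#' excitatory and inhibitory presynaptic rates:
#' `lam_E = (sigma2 + a_I * mu) / (a_E * (a_E + a_I))` and
#' `lam_I = (sigma2 - a_E * mu) / (a_I * (a_E + a_I))`.
#' The current-input approximation can yield slightly negative solutions on
#' real data; these are clipped to zero and flagged per sample rather than
#' raising an error.
#'
#' @param stats A data frame with columns `mu` (mV/ms) and `sigma2`
#'   (mV^2/ms).
#' @inheritParams rates_to_moments
#'
#' @return The input tibble with columns `lam_E`, `lam_I` (kHz) and logical
#'   flags `clipped_E`, `clipped_I` appended.
#' @examples
#' moments_to_rates(tibble::tibble(mu = 0.12, sigma2 = 0.16))
#' @export
moments_to_rates <- function(stats, a_E = 0.11, a_I = 0.09) {
  check_psp(a_E, a_I)
  stopifnot(is.data.frame(stats), all(c("mu", "sigma2") %in% names(stats)))
  out <- dplyr::mutate(
    tibble::as_tibble(stats),
    lam_E = (.data$sigma2 + a_I * .data$mu) / (a_E * (a_E + a_I)),
    lam_I = (.data$sigma2 - a_E * .data$mu) / (a_I * (a_E + a_I)),
    clipped_E = .data$lam_E < 0,
    clipped_I = .data$lam_I < 0,
    lam_E = pmax(.data$lam_E, 0),
    lam_I = pmax(.data$lam_I, 0)
  )
  out
}

check_psp <- function(a_E, a_I) {
  if (length(a_E) != 1 || length(a_I) != 1 || !is.finite(a_E) || !is.finite(a_I) ||
      a_E <= 0 || a_I <= 0) {
    stop("PSP amplitudes `a_E` and `a_I` must be single positive numbers.",
         call. = FALSE)
  }
  invisible(NULL)
}

#' Simulate the OU-plus-afterhyperpolarization voltage model
#'
#' Integrates `dU/dt = -(U - u0)/tau_m + mu(t) + sigma(t) * xi(t)` by
#' Euler-Maruyama and adds the spike after-effect kernel evaluated at the lag
#' since the most recent spike: `V(t) = U(t) + h(t - t_f)`.  Spike times are
#' supplied externally; the potential `U` evolves unaffected by them.
#'
#' @param n Number of samples.
#' @param dt Time step (ms).  Steps at or below 0.1 ms keep the
#'   Euler-Maruyama discretization bias of the stationary variance below
#'   about `dt / (2 * tau_m)` (relative), i.e. under 0.2% at the default
#'   membrane time constant.
#' @param tau_m,u0 Membrane time constant (ms) and resting potential (mV).
#' @param mu Input mean path (mV/ms); scalar or length-`n` vector.
#' @param sigma2 Input variance path (mV^2/ms, non-negative); scalar or
#'   length-`n` vector.
#' @param kernel An [ahp_kernel()] object, or `NULL` for no after-effect.
#' @param spikes Numeric vector of spike onset times (ms), sorted.
#' @param U0 Initial potential (mV); defaults to `u0`.
#' @param seed Optional integer seed for reproducibility.
#'
#' @return A tibble with columns `time` (ms), `v` (mV, potential plus
#'   kernel) and `u` (mV, kernel-free potential).
#' @examples
#' tr <- simulate_ou_ahp(1000, dt = 0.1, mu = 0.12, sigma2 = 0.16, seed = 1)
#' head(tr)
#' @export
simulate_ou_ahp <- function(n, dt = 0.1, tau_m = 26, u0 = -65.5,
                            mu = 0, sigma2 = 0, kernel = NULL,
                            spikes = numeric(0), U0 = u0, seed = NULL) {
  stopifnot(n >= 1, dt > 0, tau_m > 0)
  if (!is.null(seed)) set.seed(seed)
  mu <- rep_len(mu, n)
  sigma2 <- rep_len(sigma2, n)
  if (any(sigma2 < 0)) stop("`sigma2` must be non-negative.", call. = FALSE)
  time <- (seq_len(n) - 1L) * dt
  # U_{j+1} = a U_j + b_j with constant a: a linear recursive filter.
  a <- 1 - dt / tau_m
  noise <- if (all(sigma2 == 0)) numeric(n) else sqrt(sigma2 * dt) * stats::rnorm(n)
  b <- (dt / tau_m) * u0 + mu * dt + noise
  u <- numeric(n)
  u[1] <- U0
  if (n > 1) {
    u[-1] <- stats::filter(b[-n], a, method = "recursive", init = U0)
  }
  v <- u + eval_ahp(kernel, lag_since_spike(time, spikes))
  tibble::tibble(time = time, v = as.numeric(v), u = as.numeric(u))
}

# Lag since the most recent spike at or before each time; Inf if none.
lag_since_spike <- function(time, spikes) {
  if (length(spikes) == 0) return(rep(Inf, length(time)))
  spikes <- sort(spikes)
  idx <- findInterval(time, spikes)
  lag <- rep(Inf, length(time))
  has <- idx > 0
  lag[has] <- time[has] - spikes[idx[has]]
  lag
}

#' Model-predicted voltage band
#'
#' Under stationary input statistics the potential fluctuates around
#' `u0 + mu * tau_m` with variance `sigma2 * tau_m / 2`; adding the
#' after-effect kernel at the lag since the most recent spike gives the
#' predicted mean voltage, and +/- 1.96 stationary standard deviations give
#' pointwise 95% bounds.
#'
#' @param time Numeric vector of times (ms) at which to evaluate the band.
#' @inheritParams simulate_ou_ahp
#' @param mu,sigma2 Stationary input mean (mV/ms) and variance (mV^2/ms).
#'
#' @return A tibble with columns `time`, `mean`, `lower`, `upper` (mV).
#' @export
predictive_band <- function(time, tau_m = 26, u0 = -65.5, mu = 0, sigma2 = 0.16,
                            kernel = NULL, spikes = numeric(0)) {
  sm <- stationary_moments(mu, sigma2, tau_m, u0)
  m <- sm$mean + eval_ahp(kernel, lag_since_spike(time, spikes))
  half <- 1.96 * sqrt(sm$variance)
  tibble::tibble(time = time, mean = m, lower = m - half, upper = m + half)
}
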