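#' Full pipeline configuration
#'
#' Bundles every constant of the estimation chain: preprocessing
#' thresholds, the fixed membrane constants, PSP amplitudes, hyperparameter
#' caps and the analysis windows.  Serializable to JSON with
#' [write_pipeline_config()].
#'
#' @param preprocess A [preprocess_config()].
#' @param tau_m Membrane time constant (ms), or `NULL` to estimate it from
#'   the trace autocorrelation.
#' @param u0 Resting potential (mV).  Estimates of the input mean depend
#'   strongly on this choice; it is fixed here, not fitted.
#' @param a_E,a_I PSP amplitudes (mV) used for the moment-to-rate inversion.
#' @param hp_caps Upper bounds `c(gamma_M, gamma_S)` of the random-walk
#'   hyperparameters.
#' @param ahp_support Support of the afterhyperpolarization kernel (ms).
#' @param fit_lag_range Lag window (ms) for the membrane-time-constant fit.
#' @param stim_window `c(start, end)` (ms) of the stimulated analysis
#'   window.
#' @param ref_windows List of `c(start, end)` unstimulated reference
#'   windows, pooled per trace.
#' @param em_max_iter,em_tol EM iteration cap and convergence tolerance.
#' @param seed Default seed for stochastic pipeline stages.
#'
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(preprocess = preprocess_config(),
                            tau_m = NULL, u0 = -65.5,
                            a_E = 0.11, a_I = 0.09,
                            hp_caps = c(0.02, 0.01),
                            ahp_support = 500,
                            fit_lag_range = c(5, 50),
                            stim_window = c(1000, 2000),
                            ref_windows = list(c(500, 1000), c(2000, 2500)),
                            em_max_iter = 50, em_tol = 1e-4,
                            seed = 1L) {
  check_psp(a_E, a_I)
  structure(list(preprocess = preprocess, tau_m = tau_m, u0 = u0,
                 a_E = a_E, a_I = a_I, hp_caps = hp_caps,
                 ahp_support = ahp_support, fit_lag_range = fit_lag_range,
                 stim_window = stim_window, ref_windows = ref_windows,
                 em_max_iter = em_max_iter, em_tol = em_tol, seed = seed),
            class = "pipeline_config")
}

#' Estimate synaptic input rates from a voltage trace
#'
#' Runs the full deterministic chain: spike detection and removal,
#' smoothing and sub-sampling, membrane-time-constant estimation (unless
#' fixed in the config), afterhyperpolarization extraction and subtraction,
#' observation building, EM hyperparameter selection, assumed-density
#' smoothing, and moment-to-rate inversion.
#'
#' @param trace A voltage trace (tibble with `time` in ms, `v` in mV).
#' @param cfg A [pipeline_config()].
#'
#' @return An object of class `estimation_result` with elements `spikes`,
#'   `tau_m`, `kernel`, `u_inf`, `hp` (EM-selected hyperparameters), `obs`,
#'   `stats` (posterior input statistics per step), `rates` (inverted rate
#'   paths with clip flags) and `cfg`.  Use [generics::tidy()] for a long
#'   per-time tibble, [generics::glance()] for a one-row summary, and
#'   [ggplot2::autoplot()] for a diagnostic figure.
#' @export
run_estimation <- function(trace, cfg = pipeline_config()) {
  trace <- as_voltage_trace(trace)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  spikes <- stage("detect_spikes", detect_spikes(trace, cfg$preprocess))
  masked <- stage("remove_spikes", remove_spikes(trace, spikes, cfg$preprocess))
  sub <- stage("smooth_and_subsample", smooth_and_subsample(masked, cfg$preprocess))
  tau_m <- if (is.null(cfg$tau_m)) {
    stage("estimate_tau_m", estimate_tau_m(sub, cfg$fit_lag_range))
  } else cfg$tau_m
  if (length(spikes) > 0) {
    ahp <- stage("extract_ahp",
                 extract_ahp(sub, spikes, support = cfg$ahp_support,
                             bin = cfg$preprocess$target_dt))
    kernel <- ahp$kernel
    u_inf <- ahp$u_inf
    u <- subtract_ahp(sub, spikes, kernel)
  } else {
    kernel <- NULL
    u_inf <- mean(sub$v[sub$valid])
    u <- sub
  }
  obs <- stage("build_observations", build_observations(u, tau_m, cfg$u0))
  hp <- stage("em_hyperparameters",
              em_hyperparameters(obs, hyperparams(caps = cfg$hp_caps),
                                 max_iter = cfg$em_max_iter, tol = cfg$em_tol))
  stats <- stage("filter_smooth", filter_smooth(obs, hp))
  rates <- moments_to_rates(
    tibble::tibble(time = stats$time, mu = stats$m_hat,
                   sigma2 = stats$sigma2_hat),
    a_E = cfg$a_E, a_I = cfg$a_I
  )
  structure(list(trace = trace, spikes = spikes, potential = u,
                 tau_m = tau_m, kernel = kernel, u_inf = u_inf,
                 obs = obs, hp = hp, stats = stats, rates = rates,
                 cfg = cfg),
            class = "estimation_result")
}

#' @export
print.estimation_result <- function(x, ...) {
  cat(sprintf(
    "<estimation_result> %d obs steps, %d spikes; tau_m = %.3g ms; gamma = (%.4g, %.4g)\n",
    nrow(x$obs), length(x$spikes), x$tau_m, x$hp$gamma_M, x$hp$gamma_S))
  cat(sprintf(
    "  mean mu = %.4g mV/ms, mean sigma2 = %.4g mV^2/ms, mean rates (E, I) = (%.4g, %.4g) kHz\n",
    mean(x$stats$m_hat), mean(x$stats$sigma2_hat),
    mean(x$rates$lam_E), mean(x$rates$lam_I)))
  invisible(x)
}

#' Calibrate PSP amplitudes and resting potential on labelled simulations
#'
#' Grid search over `(a_E, a_I, u0)` minimizing the summed squared error
#' between the true input-rate paths of labelled simulations (e.g. from
#' [scenario_suite()]) and the rates estimated from their voltage traces.
#' The estimation chain is run once per `u0` value per trace; the PSP
#' amplitudes enter only the final inversion and are swept cheaply.
#'
#' @param scenarios A tibble with a `sim` list column of [simulate_neuron()]
#'   results (as returned by [scenario_suite()]).
#' @param cfg A [pipeline_config()].
#' @param a_E_grid,a_I_grid,u0_grid Candidate values.
#'
#' @return A list with the argmin `a_E`, `a_I`, `u0` and the full error
#'   `surface` (tibble with column `sse`, mV^2-free squared kHz error).
#'   Warns when the argmin lies on the grid boundary.
#' @export
calibrate_psp <- function(scenarios, cfg = pipeline_config(),
                          a_E_grid = seq(0.07, 0.15, by = 0.02),
                          a_I_grid = seq(0.05, 0.13, by = 0.02),
                          u0_grid = cfg$u0) {
  stopifnot(nrow(scenarios) >= 1, "sim" %in% names(scenarios))
  surface <- list()
  for (u0 in u0_grid) {
    cfg_u <- cfg
    cfg_u$u0 <- u0
    fits <- lapply(scenarios$sim, function(s) {
      fit <- run_estimation(s$trace, cfg_u)
      truth <- s$rates
      idx <- findInterval(fit$stats$time, truth$time)
      idx[idx < 1] <- 1
      list(stats = fit$stats,
           true_E = truth$lam_E[idx], true_I = truth$lam_I[idx])
    })
    for (aE in a_E_grid) for (aI in a_I_grid) {
      sse <- sum(vapply(fits, function(f) {
        r <- moments_to_rates(
          tibble::tibble(mu = f$stats$m_hat, sigma2 = f$stats$sigma2_hat),
          a_E = aE, a_I = aI)
        sum((r$lam_E - f$true_E)^2 + (r$lam_I - f$true_I)^2)
      }, numeric(1)))
      surface[[length(surface) + 1]] <-
        tibble::tibble(a_E = aE, a_I = aI, u0 = u0, sse = sse)
    }
  }
  surface <- dplyr::bind_rows(surface)
  best <- surface[which.min(surface$sse), ]
  on_edge <- function(x, grid) length(grid) > 1 && (x == min(grid) || x == max(grid))
  if (on_edge(best$a_E, a_E_grid) || on_edge(best$a_I, a_I_grid) ||
      on_edge(best$u0, u0_grid)) {
    warning("Calibration argmin lies on the grid boundary; widen the grid.",
            call. = FALSE)
  }
  list(a_E = best$a_E, a_I = best$a_I, u0 = best$u0, surface = surface)
}

window_mean <- function(time, value, window) {
  sel <- time >= window[1] & time < window[2]
  if (!any(sel)) return(NA_real_)
  mean(value[sel])
}

#' Stimulated-versus-unstimulated window t-test across traces
#'
#' For each signal, computes the per-trace mean over the stimulated window
#' and the per-trace mean pooled over the unstimulated reference windows,
#' then applies Welch's two-sample t-test across traces.
#'
#' @param results A list of [run_estimation()] results, or a list of data
#'   frames each containing `time` and the signal columns.
#' @param stim_window `c(start, end)` in ms.
#' @param ref_windows List of `c(start, end)` reference windows (pooled).
#' @param signals Character vector of signal columns to test.
#'
#' @return A tibble with one row per signal: `statistic`, `p_value`,
#'   `direction` (`"increase"`/`"decrease"`), `mean_stim`, `mean_ref`.
#' @export
window_ttest <- function(results, stim_window = c(1000, 2000),
                         ref_windows = list(c(500, 1000), c(2000, 2500)),
                         signals = c("lam_E", "lam_I")) {
  paths <- lapply(results, function(r) {
    if (inherits(r, "estimation_result")) generics::tidy(r) else tibble::as_tibble(r)
  })
  if (length(paths) < 2) stop("Need at least 2 traces.", call. = FALSE)
  purrr::map_dfr(signals, function(sig) {
    stim <- vapply(paths, function(p) window_mean(p$time, p[[sig]], stim_window),
                   numeric(1))
    ref <- vapply(paths, function(p) {
      mean(vapply(ref_windows, function(w) window_mean(p$time, p[[sig]], w),
                  numeric(1)))
    }, numeric(1))
    if (stats::sd(stim) == 0 && stats::sd(ref) == 0) {
      if (all(stim == ref)) {
        return(tibble::tibble(signal = sig, statistic = 0, p_value = 1,
                              direction = "none", mean_stim = mean(stim),
                              mean_ref = mean(ref)))
      }
      stop("Zero variance across traces; t-test undefined.", call. = FALSE)
    }
    tt <- stats::t.test(stim, ref)
    tibble::tibble(signal = sig, statistic = unname(tt$statistic),
                   p_value = tt$p.value,
                   direction = if (mean(stim) > mean(ref)) "increase" else "decrease",
                   mean_stim = mean(stim), mean_ref = mean(ref))
  })
}

#' Peristimulus time histogram
#'
#' Counts spikes in bins of relative time from stimulus onset, pooled over
#' trials.
#'
#' @param spikes A list of numeric vectors of spike times (ms), one per
#'   trial, or a single vector used for every onset.
#' @param onsets Stimulus onset times (ms), one per trial (recycled against
#'   a single spike vector).
#' @param bin Bin width (ms).
#' @param range Relative-time range `c(lo, hi)` (ms).
#'
#' @return A tibble with `bin_start`, `bin_end` (ms relative to onset),
#'   `count` and `rate` (spikes per trial per ms, i.e. kHz).
#' @export
psth <- function(spikes, onsets, bin = 10, range = c(-100, 300)) {
  stopifnot(bin > 0)
  if (!is.list(spikes)) spikes <- rep(list(spikes), length(onsets))
  stopifnot(length(spikes) == length(onsets))
  rel <- unlist(purrr::map2(spikes, onsets, function(s, o) s - o))
  edges <- seq(range[1], range[2], by = bin)
  counts <- if (length(rel)) {
    rel <- rel[rel >= range[1] & rel < edges[length(edges)]]
    tabulate(findInterval(rel, edges), nbins = length(edges) - 1)
  } else {
    integer(length(edges) - 1)
  }
  tibble::tibble(bin_start = edges[-length(edges)], bin_end = edges[-1],
                 count = counts,
                 rate = counts / (length(onsets) * bin))
}

#' Stimulus-triggered average of signal paths
#'
#' Averages one or more signals over trials on a common relative-time grid:
#' `s_STA(t) = (1/K) * sum_j s(t + t_j)` for onsets `t_j`.  Accepts either
#' a single path (a long recording with many onsets) or a list of
#' per-trial paths with one onset each.
#'
#' @param paths A data frame with a `time` column and numeric signal
#'   columns, or a list of such data frames (one per onset).
#' @param onsets Stimulus onset times (ms).
#' @param rel_times Relative-time grid (ms) on which to average.
#'
#' @return A tibble with `rel_time` and the trial-averaged signals.
#' @export
stimulus_triggered_average <- function(paths, onsets,
                                       rel_times = seq(-100, 300, by = 0.9)) {
  if (is.data.frame(paths)) paths <- rep(list(paths), length(onsets))
  stopifnot(length(paths) == length(onsets))
  sig_cols <- setdiff(names(paths[[1]]), "time")
  sig_cols <- sig_cols[vapply(paths[[1]][sig_cols], is.numeric, logical(1))]
  acc <- matrix(0, length(rel_times), length(sig_cols),
                dimnames = list(NULL, sig_cols))
  for (k in seq_along(paths)) {
    p <- paths[[k]]
    tt <- onsets[k] + rel_times
    if (min(tt) < min(p$time) - 1e-9 || max(tt) > max(p$time) + 1e-9) {
      stop("Analysis window extends beyond a recording.", call. = FALSE)
    }
    for (sc in sig_cols) {
      acc[, sc] <- acc[, sc] + stats::approx(p$time, p[[sc]], xout = tt, rule = 2)$y
    }
  }
  out <- tibble::as_tibble(acc / length(paths))
  dplyr::bind_cols(tibble::tibble(rel_time = rel_times), out)
}

#' Group trials by spike count and average their input signals
#'
#' Partitions trials by the number of spikes inside the stimulus window and
#' returns the per-group stimulus-triggered average of the estimated
#' signals.
#'
#' @param spikes A list of spike-time vectors (ms), one per trial.
#' @param paths A list of per-trial signal paths (data frames with `time`
#'   and numeric columns).
#' @param onsets Stimulus onset times (ms), one per trial.
#' @param stim_window `c(start, end)` (ms) relative to onset, within which
#'   spikes are counted.
#' @param rel_times Relative-time grid for the averages.
#'
#' @return A tibble with one row per spike-count group: `n_spikes`,
#'   `n_trials`, and a list column `sta` of per-group averages.
#' @export
group_by_spike_count <- function(spikes, paths, onsets,
                                 stim_window = c(0, 100),
                                 rel_times = seq(-100, 300, by = 0.9)) {
  stopifnot(length(spikes) == length(paths), length(paths) == length(onsets))
  counts <- purrr::map2_int(spikes, onsets, function(s, o) {
    sum(s - o >= stim_window[1] & s - o < stim_window[2])
  })
  groups <- sort(unique(counts))
  purrr::map_dfr(groups, function(g) {
    sel <- counts == g
    tibble::tibble(
      n_spikes = g, n_trials = sum(sel),
      sta = list(stimulus_triggered_average(paths[sel], onsets[sel], rel_times))
    )
  })
}
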