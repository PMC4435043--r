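#' Construct / validate a voltage trace
#'
#' A voltage trace is a tibble with a strictly increasing `time` column (ms)
#' and a `v` column (mV).  All estimation functions accept any data frame
#' of this shape.
#'
#' @param time Sample times (ms), strictly increasing.
#' @param v Membrane voltage (mV), same length as `time`.
#' @return A tibble with columns `time` and `v`.
#' @export
voltage_trace <- function(time, v) {
  stopifnot(length(time) == length(v))
  if (any(diff(time) <= 0)) stop("`time` must be strictly increasing.", call. = FALSE)
  tibble::tibble(time = as.numeric(time), v = as.numeric(v))
}

as_voltage_trace <- function(x) {
  stopifnot(is.data.frame(x), all(c("time", "v") %in% names(x)))
  voltage_trace(x$time, x$v)
}

as_masked <- function(x) {
  stopifnot(is.data.frame(x), all(c("time", "v") %in% names(x)))
  x <- tibble::as_tibble(x)
  if (!"valid" %in% names(x)) x$valid <- TRUE
  x
}

#' Preprocessing configuration
#'
#' Thresholds and grid parameters used to turn a raw recording into the
#' sub-threshold, smoothed, sub-sampled series the estimator consumes.
#'
#' @param spike_threshold Voltage threshold for spike detection (mV).
#' @param onset_slope Voltage derivative defining the spike onset (mV/ms).
#' @param blank_after_onset Length of the spike waveform removed after each
#'   onset (ms).
#' @param smooth_points Moving-average window length (samples).
#' @param target_dt Analysis sampling interval after sub-sampling (ms).
#'
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(spike_threshold = -30, onset_slope = 10,
                              blank_after_onset = 4.5, smooth_points = 6,
                              target_dt = 0.9) {
  stopifnot(blank_after_onset >= target_dt, smooth_points >= 1, target_dt > 0)
  structure(list(spike_threshold = spike_threshold, onset_slope = onset_slope,
                 blank_after_onset = blank_after_onset,
                 smooth_points = smooth_points, target_dt = target_dt),
            class = "preprocess_config")
}

native_dt <- function(trace, tol = 1e-6) {
  d <- diff(trace$time)
  if (length(d) == 0) stop("Trace too short.", call. = FALSE)
  if (diff(range(d)) > tol * max(d)) {
    stop("Trace is not uniformly sampled; resample before preprocessing.",
         call. = FALSE)
  }
  stats::median(d)
}

#' Detect spikes in a uniformly sampled voltage trace
#'
#' A spike is registered at each upward crossing of the voltage threshold;
#' its onset is the earliest sample within a short backward search window
#' (3 ms) whose forward-difference slope exceeds the onset slope.  If no
#' such sample exists the crossing sample itself is the onset.  Onsets
#' falling inside the blanking window of a previous onset are merged.
#'
#' @param trace A voltage trace (tibble with `time` in ms, `v` in mV),
#'   uniformly sampled.
#' @param cfg A [preprocess_config()].
#' @param search_back Backward search window for the onset (ms).
#'
#' @return A numeric vector of spike onset times (ms), sorted.
#' @export
detect_spikes <- function(trace, cfg = preprocess_config(), search_back = 3) {
  trace <- as_voltage_trace(trace)
  dt <- native_dt(trace)
  v <- trace$v
  n <- length(v)
  cross <- which(v[-1] >= cfg$spike_threshold & v[-n] < cfg$spike_threshold) + 1L
  if (length(cross) == 0) return(numeric(0))
  slope <- c(diff(v) / dt, 0)  # forward difference; last sample has none
  back <- max(0L, as.integer(round(search_back / dt)))
  onsets <- vapply(cross, function(i) {
    lo <- max(1L, i - back)
    win <- lo:i
    hit <- win[slope[win] > cfg$onset_slope]
    trace$time[if (length(hit)) hit[1] else i]
  }, numeric(1))
  # merge onsets within one blank of the previous retained onset
  keep <- rep(TRUE, length(onsets))
  last <- onsets[1]
  for (k in seq_along(onsets)[-1]) {
    if (onsets[k] - last < cfg$blank_after_onset) keep[k] <- FALSE else last <- onsets[k]
  }
  unname(onsets[keep])
}

#' Blank the spike waveform out of a trace
#'
#' Marks all samples in `[onset, onset + blank_after_onset)` as invalid for
#' each spike; everything else is untouched.  Overlapping blanks are merged
#' with a warning.
#'
#' @inheritParams detect_spikes
#' @param spikes Numeric vector of spike onset times (ms).
#'
#' @return A masked trace: tibble with columns `time`, `v`, `valid`.
#' @export
remove_spikes <- function(trace, spikes, cfg = preprocess_config()) {
  masked <- as_masked(as_voltage_trace(trace))
  if (length(spikes) == 0) return(masked)
  spikes <- sort(spikes)
  if (any(diff(spikes) < cfg$blank_after_onset)) {
    warning("Overlapping spike blanks merged.", call. = FALSE)
  }
  for (s in spikes) {
    masked$valid[masked$time >= s & masked$time < s + cfg$blank_after_onset] <- FALSE
  }
  masked
}

#' Smooth within valid runs and sub-sample to the analysis grid
#'
#' Applies a centered `smooth_points`-point moving average inside each valid
#' run (never across a spike blank; for an even window the centre sits
#' between points, taken as 3 before / 2 after for the default 6), drops the
#' run edges that lack a full window, then decimates each run to the target
#' sampling interval by nearest-sample decimation.  Runs too short to smooth
#' are dropped with a warning.
#'
#' @param masked A masked trace from [remove_spikes()] (or any tibble with
#'   `time`, `v`, `valid`), uniformly sampled where valid.
#' @param cfg A [preprocess_config()].
#'
#' @return A masked trace on the analysis grid: `time`, `v`, `valid` (all
#'   `TRUE`); consecutive retained samples are `target_dt` apart except
#'   across spike blanks.
#' @export
smooth_and_subsample <- function(masked, cfg = preprocess_config()) {
  masked <- as_masked(masked)
  dtn <- native_dt(masked)
  k <- max(1L, as.integer(round(cfg$target_dt / dtn)))
  p <- as.integer(cfg$smooth_points)
  before <- p %/% 2L      # 3 for the default 6-point window
  after <- p - before - 1L
  runs <- split(seq_len(nrow(masked)), cumsum(c(TRUE, diff(masked$valid) != 0)))
  out <- list()
  dropped <- 0L
  for (r in runs) {
    if (!masked$valid[r[1]]) next
    if (length(r) < p) { dropped <- dropped + 1L; next }
    v <- masked$v[r]
    if (p > 1) {
      cs <- cumsum(c(0, v))
      j <- (1L + before):(length(v) - after)
      sm <- (cs[j + after + 1L] - cs[j - before]) / p
      tt <- masked$time[r][j]
    } else {
      sm <- v
      tt <- masked$time[r]
    }
    pick <- seq(1L, length(sm), by = k)
    out[[length(out) + 1L]] <- tibble::tibble(time = tt[pick], v = sm[pick])
  }
  if (dropped > 0) {
    warning(sprintf("%d valid run(s) shorter than the smoothing window dropped.",
                    dropped), call. = FALSE)
  }
  if (length(out) == 0) stop("No valid runs to smooth.", call. = FALSE)
  res <- dplyr::bind_rows(out)
  res$valid <- TRUE
  res
}

#' Estimate the membrane time constant from the voltage autocorrelation
#'
#' Computes the empirical autocorrelation of the mean-subtracted valid
#' samples on the analysis grid (pairs spanning a gap are excluded) and fits
#' a straight line to its logarithm over `fit_lag_range`, excluding the
#' small-lag region where synaptic filtering distorts the exponential decay.
#' The membrane time constant is minus the inverse slope.
#'
#' @param masked A masked trace on the analysis grid (see
#'   [smooth_and_subsample()]).
#' @param fit_lag_range Lag window (ms) used for the log-linear fit;
#'   default `c(5, 50)`.
#' @param grid_dt Grid step (ms) used to index lags; defaults to the median
#'   sampling interval.
#'
#' @return The estimated membrane time constant (ms).
#' @export
estimate_tau_m <- function(masked, fit_lag_range = c(5, 50), grid_dt = NULL) {
  masked <- as_masked(masked)
  t <- masked$time[masked$valid]
  v <- masked$v[masked$valid]
  if (is.null(grid_dt)) grid_dt <- stats::median(diff(t))
  # place samples on an integer grid; gaps become NA and drop out pairwise
  idx <- as.integer(round((t - t[1]) / grid_dt)) + 1L
  x <- rep(NA_real_, max(idx))
  x[idx] <- v - mean(v)
  max_lag <- as.integer(ceiling(fit_lag_range[2] / grid_dt))
  n <- length(x)
  ac <- vapply(0:max_lag, function(l) {
    mean(x[seq_len(n - l)] * x[seq_len(n - l) + l], na.rm = TRUE)
  }, numeric(1))
  ac <- ac / ac[1]
  lag_ms <- (0:max_lag) * grid_dt
  sel <- lag_ms >= fit_lag_range[1] & lag_ms <= fit_lag_range[2] & ac > 0
  if (sum(sel) < 3) stop("Too few positive autocorrelation lags to fit.", call. = FALSE)
  # weight by ac^2: the sampling variance of log(ac_hat) is roughly
  # var(ac_hat)/ac^2, so this is inverse-variance weighting and keeps the
  # noisy small-correlation tail from dominating the fit
  fit <- stats::lm(log(ac[sel]) ~ lag_ms[sel], weights = ac[sel]^2)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0) stop("Autocorrelation does not decay; cannot estimate tau_m.",
                       call. = FALSE)
  -1 / slope
}
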