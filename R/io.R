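#' Read / write a voltage trace as two-column text
#'
#' Whitespace-separated text with optional `#` comment lines; first column
#' time, second column voltage.  Times in seconds are converted to ms when
#' `time_unit = "s"`.
#'
#' @param path File path.
#' @param time_unit `"ms"` (default) or `"s"`.
#' @return A voltage trace tibble (`time` in ms, `v` in mV).
#' @export
read_voltage_trace <- function(path, time_unit = c("ms", "s")) {
  time_unit <- match.arg(time_unit)
  tb <- utils::read.table(path, comment.char = "#",
                          col.names = c("time", "v"))
  scale <- if (time_unit == "s") 1000 else 1
  voltage_trace(tb$time * scale, tb$v)
}

#' @rdname read_voltage_trace
#' @param trace A voltage trace tibble.
#' @export
write_voltage_trace <- function(trace, path) {
  trace <- as_voltage_trace(trace)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# time_ms v_mV", con)
  utils::write.table(trace, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read stimulus onsets from one-column text
#'
#' @inheritParams read_voltage_trace
#' @return Numeric vector of onset times (ms), sorted.
#' @export
read_onsets <- function(path, time_unit = c("ms", "s")) {
  time_unit <- match.arg(time_unit)
  x <- utils::read.table(path, comment.char = "#")[[1]]
  sort(x * if (time_unit == "s") 1000 else 1)
}

#' Write an estimated input-statistics path as tabular text
#'
#' Tab-separated with a commented header naming units: columns `t_ms`,
#' `m_hat`, `m_var`, `s_hat`, `s_var`, `sigma2_hat`.
#'
#' @param stats A tibble from [filter_smooth()].
#' @param path File path.
#' @export
write_input_stats <- function(stats, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# input statistics path",
               "# t_ms m_hat[mV/ms] m_var s_hat[log mV^2/ms] s_var sigma2_hat[mV^2/ms]"),
             con)
  utils::write.table(
    stats[, c("time", "m_hat", "m_var", "s_hat", "s_var", "sigma2_hat")],
    con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Serialize / restore a pipeline configuration as JSON
#'
#' @param cfg A [pipeline_config()].
#' @param path File path.
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  x <- unclass(cfg)
  x$preprocess <- unclass(x$preprocess)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pp <- do.call(preprocess_config, x$preprocess)
  ref <- x$ref_windows
  if (is.matrix(ref)) ref <- lapply(seq_len(nrow(ref)), function(i) ref[i, ])
  pipeline_config(
    preprocess = pp, tau_m = x$tau_m, u0 = x$u0, a_E = x$a_E, a_I = x$a_I,
    hp_caps = x$hp_caps, ahp_support = x$ahp_support,
    fit_lag_range = x$fit_lag_range, stim_window = x$stim_window,
    ref_windows = ref, em_max_iter = x$em_max_iter, em_tol = x$em_tol,
    seed = x$seed
  )
}
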