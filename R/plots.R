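#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Diagnostic plot of an estimation result
#'
#' Stacks the voltage trace, the posterior input statistics (mean and
#' variance) and the inverted excitatory/inhibitory rate paths.
#'
#' @param object An [run_estimation()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.estimation_result <- function(object, ...) {
  td <- generics::tidy(object)
  long <- dplyr::bind_rows(
    tibble::tibble(time = object$trace$time, value = object$trace$v,
                   panel = "voltage (mV)", series = "V"),
    tibble::tibble(time = td$time, value = td$mu,
                   panel = "input mean (mV/ms)", series = "mu"),
    tibble::tibble(time = td$time, value = td$sigma2,
                   panel = "input variance (mV^2/ms)", series = "sigma2"),
    tibble::tibble(time = td$time, value = td$lam_E,
                   panel = "input rates (kHz)", series = "lam_E"),
    tibble::tibble(time = td$time, value = td$lam_I,
                   panel = "input rates (kHz)", series = "lam_I")
  )
  long$panel <- factor(long$panel, unique(long$panel))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(V = "grey30", mu = "black",
                                            sigma2 = "black",
                                            lam_E = "red", lam_I = "blue")) +
    ggplot2::labs(x = "time (ms)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an afterhyperpolarization kernel
#'
#' @param object An [ahp_kernel()].
#' @param fit Optional [fit_double_exp()] result overlaid in red.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ahp_kernel <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object$table, ggplot2::aes(x = .data$lag, y = .data$h)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::labs(x = "lag since spike (ms)", y = "h (mV)") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    lag <- object$table$lag
    pred <- tibble::tibble(
      lag = lag,
      h = fit$a1 * exp(-lag / fit$tau1) + fit$a2 * exp(-lag / fit$tau2))
    p <- p + ggplot2::geom_line(data = pred, colour = "red")
  }
  p
}

#' Plot a peristimulus time histogram
#'
#' @param x A tibble from [psth()].
#' @return A ggplot object.
#' @export
plot_psth <- function(x) {
  ggplot2::ggplot(x, ggplot2::aes(x = .data$bin_start, y = .data$count)) +
    ggplot2::geom_col(width = x$bin_end[1] - x$bin_start[1],
                      just = 0, fill = "grey30") +
    ggplot2::labs(x = "time from stimulus onset (ms)", y = "spike count") +
    ggplot2::theme_minimal()
}
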