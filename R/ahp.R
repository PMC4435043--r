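#' Afterhyperpolarization kernel
#'
#' A nonparametric spike after-effect function `h(lag)` on a regular lag
#' grid, zero beyond its support.  Created directly or estimated from data
#' with [extract_ahp()].
#'
#' @param lags Lag grid since the most recent spike (ms), non-negative and
#'   increasing.
#' @param h Kernel values (mV), same length as `lags`.
#' @param support Support (ms); `h` is taken as 0 for lags beyond it.
#'   Default 500 ms.
#' @param n_per_bin Optional sample counts behind each lag bin.
#'
#' @return An object of class `ahp_kernel`.
#' @examples
#' k <- ahp_kernel(lags = seq(0, 100, by = 1), h = -5 * exp(-seq(0, 100, by = 1) / 30))
#' @export
ahp_kernel <- function(lags, h, support = 500, n_per_bin = NULL) {
  stopifnot(length(lags) == length(h), all(lags >= 0), !is.unsorted(lags),
            support > 0)
  structure(
    list(
      table = tibble::tibble(
        lag = as.numeric(lags), h = as.numeric(h),
        n = if (is.null(n_per_bin)) NA_integer_ else as.integer(n_per_bin)
      ),
      support = support
    ),
    class = "ahp_kernel"
  )
}

#' @export
print.ahp_kernel <- function(x, ...) {
  cat("<ahp_kernel> ", nrow(x$table), " lag bins, support ", x$support,
      " ms, range [", round(min(x$table$h), 3), ", ",
      round(max(x$table$h), 3), "] mV\n", sep = "")
  invisible(x)
}

# Evaluate a kernel at arbitrary lags (linear interpolation on the grid,
# 0 beyond the support or before any spike).  Used by both the simulator and
# the subtraction step so that adding and removing a kernel round-trips
# exactly.
eval_ahp <- function(kernel, lags) {
  if (is.null(kernel)) return(rep(0, length(lags)))
  stopifnot(inherits(kernel, "ahp_kernel"))
  out <- rep(0, length(lags))
  inside <- is.finite(lags) & lags <= kernel$support
  if (!any(inside)) return(out)
  out[inside] <- stats::approx(kernel$table$lag, kernel$table$h,
                               xout = lags[inside], rule = 2)$y
  out
}

#' Extract the afterhyperpolarization kernel by least squares
#'
#' Assuming stationary input over the fitted segment, the mean voltage at
#' lag `s` since the most recent spike is `E[U(inf)] + h(s)`.  Minimizing the
#' summed squared error over all samples jointly in `E[U(inf)]` and a
#' piecewise-constant-per-bin `h` has the closed-form solution: `u_inf` is
#' the mean voltage over samples with lag beyond the kernel support (where
#' `h = 0` by assumption), and each kernel bin is the mean voltage in that
#' lag bin minus `u_inf`.  Bins are centred on multiples of `bin` so that
#' on spike-aligned data the kernel is recovered exactly at the sampled
#' lags.  Empty bins are filled by linear interpolation.
#'
#' @param masked A masked trace (tibble with `time`, `v`, `valid`), e.g.
#'   from [smooth_and_subsample()]; only valid samples enter the fit.
#' @param spikes Numeric vector of spike onset times (ms).
#' @param support Kernel support (ms); the after-effect is assumed to have
#'   decayed to zero beyond it.  Default 500 ms.
#' @param bin Lag bin width (ms); defaults to the analysis grid step 0.9 ms.
#'
#' @return A list with elements `kernel` (an [ahp_kernel()]) and `u_inf`
#'   (mV, the asymptotic mean potential).
#' @export
extract_ahp <- function(masked, spikes, support = 500, bin = 0.9) {
  masked <- as_masked(masked)
  if (length(spikes) < 1) stop("At least one spike is required.", call. = FALSE)
  t <- masked$time[masked$valid]
  v <- masked$v[masked$valid]
  lag <- lag_since_spike(t, spikes)
  beyond <- lag > support
  if (!any(beyond)) {
    stop("No samples beyond the kernel support; cannot identify u_inf.",
         call. = FALSE)
  }
  u_inf <- mean(v[beyond])
  centers <- seq(0, support, by = bin)
  idx <- as.integer(round(lag[!beyond] / bin)) + 1L
  idx[idx > length(centers)] <- length(centers)
  n_bin <- tabulate(idx, nbins = length(centers))
  h <- rep(NA_real_, length(centers))
  if (any(n_bin > 0)) {
    sums <- vapply(split(v[!beyond], factor(idx, levels = seq_along(centers))),
                   sum, numeric(1))
    h[n_bin > 0] <- sums[n_bin > 0] / n_bin[n_bin > 0] - u_inf
  }
  if (anyNA(h)) {
    filled <- which(!is.na(h))
    if (length(filled) == 0) stop("No samples inside the kernel support.", call. = FALSE)
    h <- stats::approx(centers[filled], h[filled], xout = centers, rule = 2)$y
  }
  list(kernel = ahp_kernel(centers, h, support = support, n_per_bin = n_bin),
       u_inf = u_inf)
}

#' Fit a double exponential to an extracted kernel
#'
#' Fits `h(t) = a1 * exp(-t / tau1) + a2 * exp(-t / tau2)` by nonlinear
#' least squares with a multi-start grid over the two time constants
#' (amplitudes solved by linear least squares at each start), refined by
#' Levenberg-Marquardt from the best start.  Components are ordered so that
#' `tau1 <= tau2`.
#'
#' @param kernel An [ahp_kernel()].
#' @param tau1_grid,tau2_grid Starting values (ms) for the fast and slow
#'   time constants.
#'
#' @return An object of class `ahp_double_exp` with fields `a1`, `tau1`,
#'   `a2`, `tau2` (mV, ms) and `rss` (mV^2).  Use [generics::tidy()] /
#'   [generics::glance()] to get tibbles.
#' @export
fit_double_exp <- function(kernel, tau1_grid = c(0.5, 1, 5),
                           tau2_grid = c(20, 40, 80)) {
  stopifnot(inherits(kernel, "ahp_kernel"))
  tb <- kernel$table
  x <- tb$lag
  y <- tb$h
  if (all(abs(y) < 1e-12)) {
    fit <- list(a1 = 0, tau1 = tau1_grid[1], a2 = 0, tau2 = tau2_grid[1],
                rss = 0, converged = TRUE)
    return(structure(fit, class = "ahp_double_exp"))
  }
  starts <- expand.grid(tau1 = tau1_grid, tau2 = tau2_grid)
  lin_amp <- function(tau1, tau2) {
    X <- cbind(exp(-x / tau1), exp(-x / tau2))
    cf <- tryCatch(unname(stats::coef(stats::lm.fit(X, y))),
                   error = function(e) c(0, 0))
    cf[!is.finite(cf)] <- 0
    rss <- sum((y - X %*% cf)^2)
    list(a = cf, rss = rss)
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    la <- lin_amp(starts$tau1[i], starts$tau2[i])
    if (is.null(best) || la$rss < best$rss) {
      best <- list(a1 = la$a[1], tau1 = starts$tau1[i],
                   a2 = la$a[2], tau2 = starts$tau2[i], rss = la$rss)
    }
  }
  df <- data.frame(x = x, y = y)
  # a vanishing amplitude makes its time constant unidentifiable (singular
  # Jacobian); nudge it so Levenberg-Marquardt can still move
  nudge <- function(a) if (abs(a) < 1e-6) 1e-3 * max(abs(y)) else a
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a1 * exp(-x / tau1) + a2 * exp(-x / tau2),
      data = df,
      start = list(a1 = nudge(best$a1), tau1 = best$tau1,
                   a2 = nudge(best$a2), tau2 = best$tau2),
      lower = c(-Inf, 1e-3, -Inf, 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    out <- list(a1 = unname(cf["a1"]), tau1 = unname(cf["tau1"]),
                a2 = unname(cf["a2"]), tau2 = unname(cf["tau2"]),
                rss = sum(stats::residuals(fit)^2), converged = TRUE)
  } else {
    # profiled refinement: optimize the time constants with the amplitudes
    # solved linearly -- immune to the singular Jacobian of a vanishing
    # component that defeats Levenberg-Marquardt
    prof <- stats::optim(log(c(best$tau1, best$tau2)), function(lt) {
      lin_amp(exp(lt[1]), exp(lt[2]))$rss
    }, method = "Nelder-Mead", control = list(maxit = 500))
    taus <- exp(prof$par)
    la <- lin_amp(taus[1], taus[2])
    out <- list(a1 = la$a[1], tau1 = taus[1], a2 = la$a[2], tau2 = taus[2],
                rss = la$rss, converged = prof$convergence == 0)
    if (!out$converged) {
      warning("Double-exponential refinement did not converge; returning the best profiled fit.",
              call. = FALSE)
    }
  }
  if (out$tau1 > out$tau2) {
    out[c("a1", "tau1", "a2", "tau2")] <- out[c("a2", "tau2", "a1", "tau1")]
  }
  structure(out, class = "ahp_double_exp")
}

#' @export
print.ahp_double_exp <- function(x, ...) {
  cat(sprintf(
    "<ahp_double_exp> h(t) = %.3g exp(-t/%.3g) + %.3g exp(-t/%.3g)  [mV, ms]; rss = %.4g mV^2\n",
    x$a1, x$tau1, x$a2, x$tau2, x$rss))
  invisible(x)
}

#' Subtract the spike after-effect from a voltage trace
#'
#' Computes the kernel-free potential `U(t) = V(t) - h(t - t_f)` using the
#' most recent spike before each sample; samples before the first spike (or
#' beyond the kernel support) are left untouched.
#'
#' @inheritParams extract_ahp
#' @param kernel An [ahp_kernel()], or `NULL` for no subtraction.
#'
#' @return The input masked trace with `v` replaced by the potential `U`.
#' @export
subtract_ahp <- function(masked, spikes, kernel) {
  masked <- as_masked(masked)
  masked$v <- masked$v - eval_ahp(kernel, lag_since_spike(masked$time, spikes))
  masked
}

#' Write / read an AHP kernel as two-column text
#'
#' Plain whitespace-separated text with comment header lines (`#`), columns
#' `lag_ms` and `h_mV`.
#'
#' @param kernel An [ahp_kernel()].
#' @param path File path.
#' @return `write_ahp_kernel()` returns `path` invisibly; `read_ahp_kernel()`
#'   returns an [ahp_kernel()].
#' @export
write_ahp_kernel <- function(kernel, path) {
  stopifnot(inherits(kernel, "ahp_kernel"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# afterhyperpolarization kernel h(lag)",
               sprintf("# support_ms: %g", kernel$support),
               "# lag_ms h_mV"), con)
  utils::write.table(kernel$table[, c("lag", "h")], con,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_ahp_kernel
#' @export
read_ahp_kernel <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# support_ms:", lines, value = TRUE)
  support <- if (length(hdr)) as.numeric(sub("^# support_ms:", "", hdr[1])) else 500
  tb <- utils::read.table(text = lines[!startsWith(lines, "#")],
                          col.names = c("lag", "h"))
  ahp_kernel(tb$lag, tb$h, support = support)
}
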