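#' Parameters of the single-compartment conductance-based neuron
#'
#' Membrane and synapse parameters of the validation simulator.  Areal
#' densities (`C_m` in uF/cm^2, `g_L` in mS/cm^2) are converted with the
#' membrane `area` to the absolute values used in integration: with the
#' defaults, total capacitance 0.35 nF and leak conductance 3.5 nS.
#'
#' @param C_m Specific membrane capacitance (uF/cm^2).
#' @param g_L Specific leak conductance (mS/cm^2).
#' @param E_L Leak reversal / resting potential (mV).
#' @param area Membrane area (um^2).
#' @param N_E,N_I Numbers of excitatory / inhibitory presynaptic neurons.
#' @param gbar_E,gbar_I Peak synaptic conductances per presynaptic spike (nS).
#' @param V_E,V_I Synaptic reversal potentials (mV).
#' @param tau_E,tau_I Synaptic decay time constants (ms).
#' @param dt Integration time step (ms).
#' @param conductance_mode `"reset"` (each presynaptic neuron's conductance
#'   jumps to `gbar` at its most recent spike) or `"sum"` (spikes add).  At
#'   the default per-neuron rates the two are numerically indistinguishable;
#'   the reset form is the model definition, the sum form is provided for
#'   sensitivity analysis.
#'
#' @return A list of class `cond_model_params`, including the derived
#'   absolute capacitance `C_nF` (nF) and leak `gL_nS` (nS).
#' @export
cond_model_params <- function(C_m = 1.0, g_L = 0.01, E_L = -70, area = 3.5e4,
                              N_E = 1000, N_I = 1000,
                              gbar_E = 1.2, gbar_I = 3.0,
                              V_E = 0, V_I = -75,
                              tau_E = 1.0, tau_I = 2.0, dt = 0.01,
                              conductance_mode = c("reset", "sum")) {
  stopifnot(C_m > 0, g_L > 0, area > 0, gbar_E > 0, gbar_I > 0,
            tau_E > 0, tau_I > 0, V_I < V_E, dt > 0)
  area_cm2 <- area * 1e-8
  structure(list(
    C_m = C_m, g_L = g_L, E_L = E_L, area = area,
    N_E = N_E, N_I = N_I, gbar_E = gbar_E, gbar_I = gbar_I,
    V_E = V_E, V_I = V_I, tau_E = tau_E, tau_I = tau_I, dt = dt,
    conductance_mode = match.arg(conductance_mode),
    C_nF = C_m * area_cm2 * 1e3,   # uF/cm^2 * cm^2 -> uF; * 1e3 -> nF
    gL_nS = g_L * area_cm2 * 1e6   # mS/cm^2 * cm^2 -> mS; * 1e6 -> nS
  ), class = "cond_model_params")
}

#' Rectangular stimulus protocol for the presynaptic rates
#'
#' Total presynaptic rates follow
#' `lam(t) = lam0 + dlam * [t_on < t <= t_on + duration]`.
#'
#' @param lamE0,lamI0 Baseline total excitatory / inhibitory rates (kHz).
#' @param dlamE,dlamI Rate increments during the stimulus (kHz); the rate
#'   must remain non-negative throughout.
#' @param t_on Stimulus onset (ms).
#' @param duration Stimulus duration (ms).
#' @return A list of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(lamE0 = 1.8, lamI0 = 2.0, dlamE = 0, dlamI = 0,
                              t_on = 1000, duration = 1000) {
  stopifnot(duration > 0, lamE0 >= 0, lamI0 >= 0,
            lamE0 + dlamE >= 0, lamI0 + dlamI >= 0)
  structure(list(lamE0 = lamE0, lamI0 = lamI0, dlamE = dlamE, dlamI = dlamI,
                 t_on = t_on, duration = duration),
            class = "stimulus_protocol")
}

rate_segments <- function(lam0, dlam, t_on, duration, t_max) {
  brk <- sort(unique(pmin(pmax(c(0, t_on, t_on + duration, t_max), 0), t_max)))
  brk <- brk[!duplicated(brk)]
  starts <- brk[-length(brk)]
  ends <- brk[-1]
  mids <- (starts + ends) / 2
  rate <- lam0 + dlam * (mids > t_on & mids <= t_on + duration)
  tibble::tibble(start = starts, end = ends, rate = rate)
}

#' Generate Poisson presynaptic spike trains
#'
#' Independent Poisson processes across `n_neurons` presynaptic neurons
#' sharing the total population rate equally: events are drawn from the
#' merged process (piecewise-constant total rate) and assigned to neurons
#' uniformly at random, which is distributionally identical.
#'
#' @param n_neurons Number of presynaptic neurons.
#' @param segments Tibble with columns `start`, `end` (ms) and `rate`
#'   (total kHz) describing the piecewise-constant total rate, or a single
#'   number taken as a constant rate on `c(0, t_max)`.
#' @param t_max Needed only when `segments` is a single rate.
#' @param seed Optional integer seed.
#'
#' @return A tibble with columns `neuron` (integer) and `time` (ms),
#'   ordered by time.
#' @export
generate_presynaptic_spikes <- function(n_neurons, segments, t_max = NULL,
                                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.numeric(segments) && length(segments) == 1) {
    stopifnot(!is.null(t_max))
    segments <- tibble::tibble(start = 0, end = t_max, rate = segments)
  }
  if (any(segments$rate < 0)) stop("Rates must be non-negative.", call. = FALSE)
  times <- unlist(lapply(seq_len(nrow(segments)), function(i) {
    len <- segments$end[i] - segments$start[i]
    n <- stats::rpois(1, segments$rate[i] * len)
    if (n == 0) return(numeric(0))
    segments$start[i] + stats::runif(n) * len
  }))
  if (length(times) == 0) {
    return(tibble::tibble(neuron = integer(0), time = numeric(0)))
  }
  neuron <- sample.int(n_neurons, length(times), replace = TRUE)
  ord <- order(times)
  tibble::tibble(neuron = neuron[ord], time = times[ord])
}

# Total synaptic conductance on the integration grid.  Events are binned to
# the grid; between events the total decays exponentially (exact solution of
# the linear decay), and at each event the owning neuron's conductance jumps
# to gbar ("reset": the jump is gbar minus the remnant of that neuron's
# previous spike) or by gbar ("sum").
conductance_path <- function(events, n_steps, dt, gbar, tau,
                             mode = c("reset", "sum")) {
  mode <- match.arg(mode)
  if (nrow(events) == 0) return(numeric(n_steps))
  jump <- rep(gbar, nrow(events))
  if (mode == "reset") {
    ord <- order(events$neuron, events$time)
    ev <- events[ord, ]
    gap <- c(Inf, diff(ev$time))
    gap[c(TRUE, diff(ev$neuron) != 0)] <- Inf
    j <- gbar * (1 - exp(-gap / tau))
    jump[ord] <- j
  }
  idx <- pmin.int(n_steps, floor(events$time / dt) + 1L)
  jumps <- numeric(n_steps)
  agg <- rowsum(jump, idx)
  jumps[as.integer(rownames(agg))] <- agg
  as.numeric(stats::filter(jumps, exp(-dt / tau), method = "recursive"))
}

#' Simulate the conductance-based neuron
#'
#' Generates Poisson presynaptic spike trains under the stimulus protocol,
#' builds the total excitatory and inhibitory conductance paths, and
#' integrates the membrane equation by forward Euler.  The model has no
#' spiking mechanism: the trace is purely sub-threshold.
#'
#' @param params A [cond_model_params()].
#' @param protocol A [stimulus_protocol()].
#' @param t_max Simulated duration (ms).
#' @param seed Optional integer seed (controls the presynaptic spikes).
#' @param V0 Initial voltage (mV); defaults to `E_L`.
#' @param keep_dt If not `NULL`, the returned trace is decimated to this
#'   sampling interval (ms) to save memory; the integration step is
#'   unchanged.
#'
#' @return A list of class `neuron_sim` with elements `trace` (tibble
#'   `time`, `v`), `rates` (tibble `time`, `lam_E`, `lam_I`: the true total
#'   input rates on the output grid), `params`, `protocol`, `seed`.
#' @export
simulate_neuron <- function(params = cond_model_params(),
                            protocol = stimulus_protocol(),
                            t_max = 3000, seed = NULL, V0 = NULL,
                            keep_dt = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dt <- params$dt
  n_steps <- as.integer(round(t_max / dt)) + 1L
  seg_E <- rate_segments(protocol$lamE0, protocol$dlamE, protocol$t_on,
                         protocol$duration, t_max)
  seg_I <- rate_segments(protocol$lamI0, protocol$dlamI, protocol$t_on,
                         protocol$duration, t_max)
  ev_E <- generate_presynaptic_spikes(params$N_E, seg_E)
  ev_I <- generate_presynaptic_spikes(params$N_I, seg_I)
  gE <- conductance_path(ev_E, n_steps, dt, params$gbar_E, params$tau_E,
                         params$conductance_mode)
  gI <- conductance_path(ev_I, n_steps, dt, params$gbar_I, params$tau_I,
                         params$conductance_mode)
  v <- euler_voltage(gE, gI, params$C_nF, params$gL_nS, params$E_L,
                     params$V_E, params$V_I, dt,
                     if (is.null(V0)) params$E_L else V0)
  time <- (seq_len(n_steps) - 1L) * dt
  if (!is.null(keep_dt)) {
    k <- max(1L, as.integer(round(keep_dt / dt)))
    pick <- seq(1L, n_steps, by = k)
    time <- time[pick]; v <- v[pick]
  }
  in_stim <- time > protocol$t_on & time <= protocol$t_on + protocol$duration
  rates <- tibble::tibble(
    time = time,
    lam_E = protocol$lamE0 + protocol$dlamE * in_stim,
    lam_I = protocol$lamI0 + protocol$dlamI * in_stim
  )
  structure(list(trace = tibble::tibble(time = time, v = v),
                 rates = rates, params = params, protocol = protocol,
                 seed = seed),
            class = "neuron_sim")
}

#' @export
print.neuron_sim <- function(x, ...) {
  cat(sprintf(
    "<neuron_sim> %.3g s at dt = %g ms; baseline rates %.3g/%.3g kHz, increments %.3g/%.3g kHz\n",
    max(x$trace$time) / 1000, x$params$dt,
    x$protocol$lamE0, x$protocol$lamI0, x$protocol$dlamE, x$protocol$dlamI))
  invisible(x)
}

#' The four benchmark stimulation scenarios
#'
#' Simulates labelled voltage traces for the four canonical stimulus
#' effects used to validate the estimator: pure excitation
#' (`dlamE = 0.7, dlamI = 0` kHz), strong mixed excitation and inhibition
#' (`8.7, 8.0`), mixed (`6.0, 8.0`) and no effect (`0, 0`), each on
#' baselines 1.8 / 2.0 kHz with a 1 s stimulus starting 1 s into a 3 s
#' trace.
#'
#' @param seed Base integer seed; trace `r` of scenario `s` uses
#'   `seed + 1000 * s + r` so batches are reproducible.
#' @param n_per_scenario Number of independent traces per scenario.
#' @param scenarios Optional subset of scenario names.
#' @param params A [cond_model_params()].
#' @param t_max Trace duration (ms).
#' @param keep_dt Optional output decimation (ms), passed to
#'   [simulate_neuron()].
#'
#' @return A tibble with columns `scenario`, `rep`, `seed` and a list
#'   column `sim` of [simulate_neuron()] results.
#' @export
scenario_suite <- function(seed = 1, n_per_scenario = 1,
                           scenarios = c("pure_excitation", "strong_mixed",
                                         "mixed", "no_effect"),
                           params = cond_model_params(), t_max = 3000,
                           keep_dt = NULL) {
  defs <- tibble::tibble(
    scenario = c("pure_excitation", "strong_mixed", "mixed", "no_effect"),
    dlamE = c(0.7, 8.7, 6.0, 0),
    dlamI = c(0, 8.0, 8.0, 0)
  )
  defs <- defs[defs$scenario %in% scenarios, ]
  out <- tidyr::expand_grid(defs, rep = seq_len(n_per_scenario))
  out$seed <- seed + 1000L * match(out$scenario, defs$scenario) + out$rep
  out$sim <- purrr::pmap(out[c("dlamE", "dlamI", "seed")], function(dlamE, dlamI, seed) {
    simulate_neuron(params,
                    stimulus_protocol(dlamE = dlamE, dlamI = dlamI,
                                      t_on = 1000, duration = 1000),
                    t_max = t_max, seed = seed, keep_dt = keep_dt)
  })
  out[c("scenario", "rep", "seed", "sim")]
}
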