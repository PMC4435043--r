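---
title: "Estimating excitatory and inhibitory synaptic input rates from a voltage trace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating excitatory and inhibitory synaptic input rates from a voltage trace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synrates)
```

## The problem

Whether a sensory stimulus drives a neuron through pure excitation or
through a mixture of excitation and inhibition cannot be read off a
membrane-voltage trace by eye: both produce similar-looking depolarizing
responses.  The two regimes differ, however, in how they move the first
two moments of the synaptic drive.  Excitation alone shifts the mean input
upward with only a modest change in its variance, whereas balanced
excitation and inhibition leaves the mean almost unchanged but inflates
the variance.  `synrates` turns this observation into an estimator: it
infers the time-varying input mean and input variance from a single
intracellular voltage trace and converts them to total excitatory and
inhibitory presynaptic rates.

## The generative model

The sub-threshold voltage is decomposed as

$$V(t) = U(t) + h(t - t_f),$$

where $t_f$ is the most recent spike time, $h$ is a nonparametric
afterhyperpolarization (AHP) kernel assumed to vanish beyond 500 ms, and
$U$ is an Ornstein–Uhlenbeck (OU) diffusion

$$\frac{dU}{dt} = -\frac{U - u_0}{\tau_m} + \mu(t) + \sigma(t)\,\xi(t),$$

with resting potential $u_0$ (mV), membrane time constant $\tau_m$ (ms),
input mean $\mu(t)$ (mV/ms), input variance $\sigma^2(t)$ (mV²/ms) and
unit white noise $\xi$.  The process is *not* reset at spikes; the spike
after-effect is purely additive.  For stationary input the potential is
Gaussian with mean $u_0 + \mu\tau_m$ and variance $\sigma^2\tau_m/2$.

Under a diffusion approximation of summed Poisson synaptic impulses with
delta-shaped post-synaptic potentials of amplitudes $a_E$, $a_I$ (mV),

$$\mu = a_E\lambda_E - a_I\lambda_I, \qquad
  \sigma^2 = a_E^2\lambda_E + a_I^2\lambda_I,$$

which inverts in closed form to the total input rates (kHz)

$$\lambda_E = \frac{\sigma^2 + a_I\mu}{a_E(a_E + a_I)}, \qquad
  \lambda_I = \frac{\sigma^2 - a_E\mu}{a_I(a_E + a_I)}.$$

Real data occasionally produce slightly negative solutions (the
current-input approximation ignores conductance effects);
`moments_to_rates()` clips these at zero and flags the affected samples
rather than failing.

All quantities are carried internally in mV, ms and kHz (events/ms); every
printed default below is in those units.

## The estimation chain

`run_estimation()` applies, in order:

1. **Spike detection and removal** (`detect_spikes()`, `remove_spikes()`).
   A spike is an upward crossing of −30 mV; its onset is the earliest
   sample within a 3 ms backward window whose forward-difference slope
   exceeds 10 mV/ms; the 4.5 ms after each onset is blanked.
2. **Smoothing and sub-sampling** (`smooth_and_subsample()`).  A centred
   6-point moving average inside each valid run (never across a blank),
   then decimation to a 0.9 ms analysis grid.  For an even window the
   centre is taken as 3 points before, 2 after; a trailing window would
   only add a fixed phase shift.
3. **Membrane time constant** (`estimate_tau_m()`), unless fixed in the
   configuration: a weighted log-linear fit to the voltage
   autocorrelation.  See *Numerical choices* below for the lag window.
4. **AHP extraction and subtraction** (`extract_ahp()`,
   `subtract_ahp()`).  Assuming stationary input over the fitted segment,
   minimizing $\sum_t \{V(t) - E[U(\infty)] - h(t-t_f)\}^2$ over the
   asymptotic level and a piecewise-constant kernel has a closed-form
   solution: the level is the mean voltage at lags beyond the kernel
   support, and each kernel bin is the mean voltage in that lag bin minus
   the level.  Bins are centred on multiples of the 0.9 ms grid step, so
   on spike-aligned data the kernel is exact at the sampled lags.
   `fit_double_exp()` optionally summarizes the kernel as
   $a_1 e^{-t/\tau_1} + a_2 e^{-t/\tau_2}$.
5. **State-space smoothing** (`build_observations()`, `filter_smooth()`).
   Discretizing the OU dynamics gives per-step observations
   $Z_j = U_{j+1} - U_j + (\Delta_j/\tau_m)(U_j - u_0)$ with
   $Z_j \sim N(M_j\Delta_j,\; e^{S_j}\Delta_j)$, where $M_j$ is the input
   mean and $S_j$ the *log* input variance — the exponential guarantees a
   positive variance estimate.  Independent Gaussian random walks with
   scales $\gamma_M$, $\gamma_S$ act as smoothness priors.  Steps spanning
   a spike blank carry no observation and only propagate the prior.
6. **Hyperparameter selection** (`em_hyperparameters()`):
   expectation–maximization with the closed-form M-step
   $\gamma^2 = \operatorname{mean}_j E[(X_{j+1}-X_j)^2]/\Delta_j$,
   capped at $\gamma_M \le 0.02$, $\gamma_S \le 0.01$ to prevent the
   estimates from chasing noise.
7. **Rate inversion** (`moments_to_rates()`) with the configured
   $a_E$, $a_I$.

### The approximate smoother

The observation density is Gaussian in $M_j$ but not in $S_j$, so exact
inference is intractable.  The forward pass is an assumed-density filter:
each measurement update first locates the per-step posterior by Newton
iteration (a Laplace fit), then replaces the mode and curvature by the
posterior *mean and covariance* computed with 9×9-point Gauss–Hermite
quadrature centred on the Laplace Gaussian.  The distinction matters
because the variance posterior is skewed: matching modes biases $S$
low.  A Rauch–Tung–Striebel pass smooths the Gaussian sequence, and two
expectation-propagation sweeps then re-derive each observation's Gaussian
site against its cavity under the smoothed approximation.  On a 500-step
test series the result agrees with an exact dense-grid forward–backward
solver to better than 0.01 posterior standard deviations in both
components; the one-pass smoother without the refinement is visibly biased
(about 0.15 SD) in the log-variance component.

Two independent cross-checks guard this construction: with the variance
state frozen the code must reproduce a textbook Kalman smoother to
1e-8, and on nonlinear series it must agree with `particle_smoother()`, a
bootstrap particle filter with systematic resampling and a
backward-simulation smoother that converges to the exact posterior as the
particle count grows.

### EM acceleration

The plain EM map for a random-walk scale contracts arbitrarily slowly
when the optimum is at or near zero (static input) or at a cap.  Each EM
cycle therefore applies Aitken $\Delta^2$ extrapolation per component when
the iterate contracts geometrically, and proposes the nearest boundary
when it accelerates; every proposal is kept only if it does not decrease
the approximate marginal likelihood.  Iteration stops when the
hyperparameters stabilize or the likelihood gain per cycle falls below
0.01, where the profile is flat enough that further digits do not change
the smoothed paths.

## The validation simulator

Because real intracellular recordings with known input rates do not
exist, the estimator is validated against a single-compartment
conductance-based neuron (`simulate_neuron()`):

$$C_m \frac{dV}{dt} = -g_L(V - E_L)
  - \sum_k g_{E,k}(t)(V - V_E) - \sum_k g_{I,k}(t)(V - V_I),$$

with 1000 excitatory and 1000 inhibitory presynaptic Poisson neurons,
exponential-decay conductances ($\bar g_E = 1.2$ nS, $\tau_E = 1$ ms;
$\bar g_I = 3$ nS, $\tau_I = 2$ ms; $V_E = 0$, $V_I = -75$ mV), leak
$g_L = 0.01$ mS/cm², $C_m = 1$ μF/cm², $E_L = -70$ mV over a
3.5×10⁴ μm² membrane (totals: 3.5 nS, 0.35 nF), integrated by forward
Euler at 0.01 ms.  A presynaptic spike *resets* that neuron's conductance
to $\bar g$; at the default per-neuron rates (≈2 Hz) this differs from
additive summation only in rare coincident-spike transients
(`conductance_mode = "sum"` is available for sensitivity analysis).
Stimuli are rectangular rate steps: baselines 1.8 / 2.0 kHz, increments
$\delta\lambda_E$, $\delta\lambda_I$ for 1 s.  `scenario_suite()` bundles
the four canonical cases — pure excitation (0.7, 0), strong mixed
(8.7, 8.0), mixed (6.0, 8.0), no effect (0, 0).

What the simulator deliberately does **not** emulate: spike-generating
currents (traces are purely sub-threshold; spike-handling code is
exercised on constructed traces instead), dendritic structure, correlated
presynaptic activity, and synaptic short-term plasticity.  Passing the
scenario tests therefore shows that the estimator works when its main
assumption — current-like, independent-Poisson input — is only mildly
violated (conductance input), not that it is robust to every property of
real recordings.

Two systematic effects of the conductance mismatch are expected and
reproduced rather than hidden: estimated rates are *underestimated*
during strong stimulation, and under pure excitation the method reports a
spurious *decrease* in inhibition, because an inhibition drop is the
current-model's only way to express the unchanged variance-to-mean
relation.  Both appear in the scenario validation tests.

## Numerical choices

* **Membrane-time-constant fit window** (default 5–50 ms).  The voltage
  autocorrelation of the conductance model departs from a single
  exponential at small lags (synaptic time constants of 1–2 ms and the
  smoothing filter distort it); the local decay constant plateaus from
  about 5 ms.  Beyond ~50 ms the autocorrelation (< 0.1) is
  noise-dominated.  The log-fit uses weights proportional to the squared
  autocorrelation — inverse-variance weighting for a log-transformed
  estimate.  Against the analytic effective-conductance value
  $C/(g_L + \bar g_E\lambda_E\tau_E + \bar g_I\lambda_I\tau_I)
  \approx 19.8$ ms the estimator is unbiased to within a few percent; a
  single 20-s segment still carries ~3 ms sampling spread, so replicate
  segments are pooled (harmonic mean — decay rates average) whenever a
  stable value is needed.
* **Initial state prior**: mean = static moment-matched estimates
  ($\hat M = \sum Z_j / \sum \Delta_j$; $\hat S$ from the residual second
  moment), variance = 10× the per-step random-walk variance at the caps.
  It is forgotten within a few steps but keeps both the Gaussian and the
  particle smoother well-conditioned.
* **Degenerate updates**: non-positive-definite 2×2 matrices are jittered
  by 1e-10 and retried; pinned components (zero prior variance, used to
  freeze the variance state in cross-checks) bypass the EP refinement
  through exact scalar formulas.
* **Double-exponential fits**: multi-start over
  $\tau_1 \in \{0.5, 1, 5\}$, $\tau_2 \in \{20, 40, 80\}$ ms with
  amplitudes solved linearly, refined by Levenberg–Marquardt; if a
  vanishing amplitude makes the Jacobian singular, a profiled Nelder–Mead
  refinement over the time constants is used instead.
* **Sub-sampling** is nearest-sample decimation (no interpolation); the
  spike blank leaves one wide step in the $\Delta_j$ sequence, which the
  state-space model handles through its per-step $\Delta_j$.
* **Seeds**: every stochastic function takes an explicit `seed` and is
  bit-reproducible; batch helpers derive per-trace seeds from a base seed.

## Problem sizes used in the shipped validation

The test suite and the acceptance script run everything at desk scale,
chosen so that each check is decisively more precise than the tolerance
it asserts: stationary-moment and coverage checks on 10⁵–10⁶-step OU
paths; parameter recovery on 15 s of synthetic data at the 0.9 ms grid;
scenario discrimination with 20 replicate 3-s traces per scenario;
smoother-versus-particle-oracle agreement on a 500-step series with two
averaged 60 000-particle runs (accuracy-equivalent to a single
~120 000-particle run); and the effective-time-constant benchmark pooled
over 20–25 replicate 20-s baseline segments.

## Known limitations

* The estimator assumes current-like input; strong conductance changes
  bias the inversion (underestimated rates, spurious inhibition changes
  under pure excitation), as quantified by the scenario tests.
* $u_0$ is fixed, not estimated, and $\hat\mu$ depends strongly on it;
  it is exposed in `pipeline_config()` and can be calibrated together
  with $a_E$, $a_I$ on labelled simulations via `calibrate_psp()`.
* The random-walk priors cannot track input changes much faster than the
  analysis grid and the capped $\gamma$ allow; onset-latency differences
  below ~10 ms are smoothed over.
* The delta-PSP assumption behind the moment equations ignores the 1–2 ms
  synaptic time constants; the resulting error is not modelled.
* File I/O is plain text only; very long recordings should be processed
  in segments.

## A worked example

```{r example, eval = FALSE}
library(synrates)

# simulate a mixed excitation-and-inhibition stimulation episode
sim <- simulate_neuron(
  protocol = stimulus_protocol(dlamE = 6, dlamI = 8),
  t_max = 3000, seed = 21)

# estimate the input statistics and rates from the voltage trace alone
fit <- run_estimation(sim$trace, pipeline_config(tau_m = 19))
fit
glance(fit)

# compare windows: stimulated (1-2 s) vs unstimulated (0.5-1, 2-2.5 s)
tidy(fit) |>
  dplyr::mutate(window = dplyr::case_when(
    time >= 1000 & time < 2000 ~ "stimulated",
    (time >= 500 & time < 1000) | (time >= 2000 & time < 2500) ~ "reference",
    TRUE ~ NA_character_)) |>
  dplyr::filter(!is.na(window)) |>
  dplyr::group_by(window) |>
  dplyr::summarise(dplyr::across(c(mu, sigma2, lam_E, lam_I), mean))

autoplot(fit)
```
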