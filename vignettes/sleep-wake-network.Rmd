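---
title: "A three-population firing-rate model of the sleep-wake cycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A three-population firing-rate model of the sleep-wake cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepnet)
```

## The model

`sleepnet` simulates a deliberately abstract sleep-wake regulatory circuit:
three neural populations, each named for the vigilance state it promotes
(Wake, NREM sleep, REM sleep), coupled by six weighted synaptic pathways and
driven by a homeostatic sleep pressure. The population activity is a
firing-rate variable $F_X$ relaxing toward a saturating function of its
summed synaptic input,

$$\frac{dF_X}{dt} = \frac{F_{X\infty}(I_X) - F_X}{\tau_X},\qquad
F_{X\infty}(I) = X_{max}\cdot\tfrac12\left(1 + \tanh\frac{I-\beta_X}{\alpha_X}\right),$$

with one twist for the NREM population: its activation threshold is not a
constant but $k_N H(t)$, where $H$ is the homeostatic sleep drive. With
$k_N < 0$ (the package default), rising sleep pressure makes the NREM
population progressively easier to activate — this is the mechanism that
converts sustained wakefulness into sleep onset.

Each population releases a transmitter whose concentration $C_Y \in [0,1]$
tracks the firing rate through its own saturating kinetics,

$$\frac{dC_Y}{dt} = \frac{\tanh(F_Y/\gamma_{C_Y}) - C_Y}{\tau_{C_Y}},$$

and the synaptic inputs are weighted sums of these concentrations plus weak
Gaussian noise $\xi$ (mean 0.01 Hz, s.d. 0.005 Hz, one independent draw per
population per integration step):

$$I_W = g_{NWi}C_N + g_{RWe}C_R + \xi,\quad
I_N = g_{WNi}C_W + \xi,\quad
I_R = g_{WRi}C_W + g_{NRi}C_N + g_{RRe}C_R + \xi.$$

The homeostat builds during wake-level activity of the Wake population and
decays otherwise:

$$\frac{dH}{dt} = \frac{H_{max}-H}{\tau_{hw}}\,\mathcal H(F_W-\theta_W)
  - \frac{H}{\tau_{hs}}\,\mathcal H(\theta_W-F_W),$$

with $\mathcal H$ the Heaviside function, $\mathcal H(0)=1$. Note a
consequence of that convention: at $F_W$ exactly equal to $\theta_W$ *both*
indicator terms fire. The package implements the equation literally.

A note on bookkeeping: the transmitter equations are written per pathway
($C_{YX}$), but the input equations reference a single concentration per
source population. The package therefore carries one concentration state per
source (three variables), shared by all of its targets — the minimal choice
consistent with the input equations. Similarly, one symbol does double duty
in the transmitter equation as both the decay constant and the in-`tanh`
scale; the package separates these into `tau_C_Y` (seconds) and `gamma_C_Y`
(Hz) with equal numeric defaults, so the literal equations are recovered
while both remain independently configurable.

## Numerical scheme

Trajectories are integrated with the classical fixed-step fourth-order
Runge-Kutta scheme at `dt = 1` ms for 24 simulated hours. Noise is frozen
across the four stages of a step (one draw per population per step, consumed
in the fixed order W, N, R), which preserves classical RK4 semantics; no
claim of strong-order stochastic convergence is made — the noise is a small
perturbation, not the object of study. The empirical convergence order on a
scalar relaxation problem exceeds 3.9 (see `tests/` and
`scripts/acceptance.R`).

The 7-dimensional state is confined to the box
$0 \le F_X \le X_{max}$, $0 \le C_Y \le 1$, $0 \le H \le H_{max}$. The
vector field points inward on the boundary, so the box is forward-invariant;
floating-point overshoot up to `clip_tol` ($10^{-6}$) is clipped back onto
the boundary and anything larger aborts the run with the step index and the
offending component. Integration always runs at `dt`; storage is decimated
by `store_every` (default 100, i.e. a 0.1-s grid for a 1-ms step). Storing
every millisecond sample of a day-long run would cost ~5 GB and serves no
analysis need — the dynamics of interest unfold over minutes to hours — but
`store_every = 1` is available, and full-resolution extrema of every state
component are tracked regardless, so box invariance is checked at `dt`
resolution even when storage is decimated. Scoring runs on the stored grid;
this is recorded in the trajectory metadata.

## Parameters and calibration

The six control pathway weights are fixed by the perturbation design itself
(every altered condition is an exact multiple of them):

| pathway | meaning | control weight |
|---|---|---|
| RRe | REM recurrent excitation | 1.6 |
| RWe | REM → Wake excitation | 1.0 |
| WNi | Wake → NREM inhibition | −2.0 |
| WRi | Wake → REM inhibition | −4.0 |
| NRi | NREM → REM inhibition | −1.3 |
| NWi | NREM → Wake inhibition | −1.68 |

The remaining constants (maxima, slopes, thresholds, time constants) are the
package's own calibrated defaults: they were chosen once, by the scripted
grid exploration in `tools/calibrate.R`, to place the noise-free model in
the regime the model family is meant to exhibit, and have not been revisited
since. The calibration targets were: (a) the run starts in wakefulness and
all three states occur within 24 h; (b) the homeostat builds during
wake-classified samples and decays during sleep; (c) NREM and REM alternate
within a sleep phase before wakefulness returns; (d) the documented
directional responses hold (stronger WNi lengthens wakefulness, stronger WRi
shortens it, stronger RRe shortens the REM latency, an NWi lesion abolishes
sleep).

The key defaults, with the reasoning behind them:

* `W_max = N_max = R_max = 5` Hz — the scoring threshold (2 Hz) must sit
  between rest and the half-maximum of an active population.
* `alpha_* = 0.25` — sharp activation makes the mutual-inhibition motifs
  behave as flip-flop switches rather than graded mixtures.
* `beta_W = -1.1`, `beta_R = -1.2` — both populations are excitable at zero
  input (wakefulness is the default state of the unforced network; REM can
  ignite from NREM through its recurrent collateral), yet far enough below
  zero that the opposing inhibition silences them cleanly.
* `k_N = -2.5` with `H_max = 1` — NREM activation overcomes the Wake
  population's inhibition (−2 × C_W) only once H has built to roughly 3/4 of
  its ceiling, giving multi-hour wake bouts.
* `tau_W = tau_N = tau_R = 30` s — transitions unfold over minutes, slow
  against the integration step and fast against episode durations.
* `tau_hw = 3` h, `tau_hs = 1.5` h — sleep pressure builds more slowly than
  it dissipates, giving a wake-dominated day.
* `tau_C_W = gamma_C_W = 4`, `tau_C_N = gamma_C_N = 2`,
  `tau_C_R = gamma_C_R = 5` — the one genuinely structural choice. The race
  that decides whether REM can ignite inside NREM sleep is between REM's
  recurrent excitation (`RRe * C_R`) and the residual Wake inhibition
  (`WRi * C_W`). A larger Wake release scale keeps the low residual wake
  firing (~0.1 Hz) from releasing enough transmitter to strangle the REM
  ignition cascade, while barely affecting release at wake-level rates.

With these defaults the noise-free day runs roughly 61% wake / 30% NREM /
9% REM, with multi-hour wake bouts and sleep phases in which NREM and REM
alternate on a minutes scale — a compressed, rodent-like architecture. After
the first (transient-bearing) cycle the noise-free rhythm is periodic.

Initial condition: the network starts awake (`F_W = W_max`, sleep
populations silent, concentrations at their steady states for those rates,
`H = 0`); configurable through `run_simulation(init = )`.

## Scoring and metrics

A sample is scored Wake if `F_W > 2` Hz; otherwise REM if `F_R > 2` Hz;
otherwise NREM — precedence exactly in that order, comparisons strict, so
rates exactly at threshold fall through. No smoothing or minimum episode
duration is applied by default (`build_hypnogram(min_duration_s = )` exists
but defaults off). From the run-length episode encoding the package computes
total durations, percentages, episode counts, ordered transition counts, the
NREM latency (first NREM onset from the start of the record, 0 if the record
begins in NREM) and the REM latency (first REM onset at or after the first
NREM onset, minus that onset; REM occurring before any NREM is ignored for
the latency but still counted in the metrics). A latency whose state never
occurs is `NA`, a value, not an error.

## The perturbation study

`sweep_table()` enumerates the 6 pathways × 8 scale factors
(0 = lesion, 1/8, 1/4, 1/2, 1 = control, 2, 4, 8); `run_condition()` runs
`n` replicate noisy simulations per condition with seeds
`base_seed + 0:(n-1)`. Seeds are deliberately condition-independent, so
conditions differ only in the manipulated weight, never in their noise —
this maximises sensitivity to the manipulation. `run_joint_sweep()`
manipulates both output pathways of one population over a scale grid and
reports mean state percentages per cell. The statistics layer
(`one_way_anova()`, `tukey_hsd()`) is the classical k-group decomposition
(df `k−1`, `N−k`) with Tukey-Kramer post-hoc comparisons against control at
α = 0.05. Replicated simulations of a deterministic-plus-small-noise system
can produce near-zero within-group variance; `one_way_anova()` flags the
fully degenerate case instead of reporting a meaningless F.

## Synthetic fixtures

`make_synthetic_hypnogram()` builds hypnograms either from an explicit
episode list (realised exactly) or from a first-order Markov chain over the
three states with geometric dwell times at `dt` resolution — the simplest
process consistent with a per-sample chain, used purely as a test device.
`make_test_timeseries()` builds piecewise-constant rate trajectories with
admissible constant concentrations. `brute_force_metrics_oracle()`
recomputes every metric by a naive per-sample linear scan and exists only to
cross-check `compute_metrics()`; the two are developed independently and
compared exactly on thousands of random hypnograms.

What the fixtures do *not* emulate: real hypnograms have heavy-tailed bout
durations, time-of-day structure and REM-pressure dynamics. Passing the
scoring tests on synthetic data therefore validates the bookkeeping
(encoding, counting, latencies), not any biological realism of the
generator.

## Problem sizes used in the tests

Unit tests run seconds-to-minutes-long coarse-step simulations; the
acceptance suite runs the study conditions proper — 24-h days at `dt = 1` ms
for the reference run and the lesion, and a reduced-scale trend battery
(6 simulated hours, 4 replicates, scales 1/2/4/8) for the directional
effects. These sizes were chosen as the smallest at which the corresponding
qualitative claims are stable across seeds.

## Known limitations

* The model has no circadian drive, no REM-sleep homeostasis and no spiking
  dynamics; it is a caricature for studying pathway-dependent regulation,
  not a predictive model of any species' sleep.
* All manipulations are tonic (whole-simulation); transient, time-windowed
  manipulations are out of scope.
* Absolute architecture numbers (percentages, episode counts, latencies)
  depend on the calibrated defaults and should be read as properties of this
  configuration, not as biological predictions; the robust outputs are the
  directional responses to weight scaling.
* State classification reads the firing rates of the very populations being
  manipulated, so under extreme weights (e.g. strong RRe) the network can
  enter a pathological regime where Wake- and REM-promoting populations are
  simultaneously active and the record is scored Wake by precedence.

## A worked example

```{r, eval = FALSE}
library(sleepnet)

m <- sleep_model(sleep_params())
ts <- simulate(m, seed = 1)      # one noisy 24-h day, dt = 1 ms
h <- build_hypnogram(ts)
compute_metrics(h)

# the perturbation experiment, desk scale
sweep <- run_sweep(sleep_params(), pathways = "WNi", scales = c(1, 2, 4, 8),
                   replicates = 4, duration = 6 * 3600, base_seed = 1)
sweep_stats(sweep, "pct_WAKE", "WNi")
```
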