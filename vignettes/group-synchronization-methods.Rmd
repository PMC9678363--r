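---
title: "Models and methods for group synchronization analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for group synchronization analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groupsync)
```

## The scientific problem

When several people drum together in a synchronization–continuation task
(drum along with a metronome, then keep going after it stops), the ensemble
behaves as more than a set of independent timekeepers. Two empirical
signatures of this are (a) the *group aggregate* — the ensemble treated as a
single beat-producing entity — keeps time more steadily than any individual
member, and (b) this collective benefit grows with group size. `groupsync`
provides both a generative model of this phenomenon (a family of
phase-oscillator simulators) and the complete descriptive pipeline used to
quantify it in onset-time data: aggregate construction, inter-onset-interval
(IOI) metrics, correlation profiles, point-process transfer entropy, and
directed-network summaries.

## The oscillator models

Each performer is a phase oscillator `theta_i(t)` with intrinsic frequency
`omega_i` (drawn from a Gaussian in Hz, converted internally to rad/s). The
package integrates three variants with a fixed-step third-order Runge–Kutta
solver:

* **Classic Kuramoto** (`simulate_classic`):
  `dtheta_i/dt = omega_i + (K/N) * sum_j sin(theta_j - theta_i)`.
* **Mean-field form** (`simulate_meanfield`):
  `dtheta_i/dt = omega_i + r K sin(Psi - theta_i)`, with the order parameter
  `r e^{i Psi} = mean(e^{i theta_j})` recomputed at every solver stage. This
  is algebraically identical to the classic form and serves as its
  equivalence oracle in the test suite (agreement is at numerical precision,
  far below the 1e-6 rad bound we assert).
* **Hybrid pulse-coupled model** (`simulate_pulse_coupled`): coupling is
  delivered as discrete acoustic-like events. An oscillator emits a pulse
  once per cycle when its phase crosses zero; the pulse is a unit-area gamma
  density (`pulse_kernel`, shape 1.25, scale 0.02 s — sharp rise, ~200 ms
  decay), and the receiver integrates
  `dtheta_i/dt = omega_i + (K/N) * sum_{j != i} P_j(t) * s * sin(theta_i) + noise`,
  where `P_j` superposes the pulses of oscillator `j` and `s` is the
  sensitivity sign. Topologies: full, nearest-neighbor ring (periodic
  boundary), or uncoupled.

### Sign convention of the pulse sensitivity

With firing at phase zero, a `+sin(theta_i)` sensitivity *repels* the
receiver from the firing phase: simulations with the plus sign fail to
synchronize and can suppress units entirely. The attracting convention
(`pulse_sign = -1`, the default) pulls a receiver toward firing in time with
the pulses it hears and produces robust group synchronization (mean
coherence ≈ 0.86–0.94 at `K = 8`). The repelling sign remains available as a
config switch for exploration.

### Noise discretization

The phase noise is specified as a Gaussian perturbation `N(0, sigma)` of the
phase rate with `sigma = 6`. Two discretizations are provided:

* `noise_mode = "per_sample"` (default): the perturbation is treated as an
  intrinsic-frequency fluctuation held over one solver step, adding
  `sigma * dt` (rad) of phase noise per step at the default 300 Hz solver
  rate. In this mode a solo oscillator's cycle-duration CoV is ≈ 0.04,
  the scale observed in human tapping, and coupled ensembles synchronize.
* `noise_mode = "sqrt_dt"`: the Euler–Maruyama diffusion discretization
  (`sigma * sqrt(dt)` per step), which is invariant to the solver rate. At
  `sigma = 6` this injects so much phase diffusion that coupling `K = 8`
  cannot create coherence (measured mean `r` is barely above the uncoupled
  finite-size baseline) and solo CoV is ≈ 0.68, an order of magnitude above
  behavioral values.

We therefore default to `per_sample`: it is the only interpretation under
which the model exhibits the phenomenon it was built to explain —
synchronized ensembles at behavioral noise scales. The `sqrt_dt` mode is
kept for step-size-sensitivity checks (deterministic step-size robustness is
separately asserted in the tests: doubling the solver rate changes
noise-free trajectories by < 1e-4 rad at 10 s).

## The condition grid and its summary conventions

`run_condition_grid` crosses group size `N ∈ {2, 4, 8}` with coupling
`K ∈ {0 (solo), 8 (ensemble)}` and runs seeded, independent 100 s trials at
300 Hz (20 runs per condition by default in the packaged studies; the counts
and durations are stated here as the package's chosen problem sizes). For
every oscillator and for the mean field it records the CoV of cycle
durations, both raw (`cov_raw`) and after removing durations deviating more
than 50% from the unit's median (`cov_clean`) — the same relative-median
rule the behavioral pipeline applies to IOIs, which strips the
doubled/halved durations left by occasional missed or spurious crossings.

Units whose onset count is not within 50% of the count implied by their
intrinsic frequency are flagged invalid and excluded from condition
summaries (`summarize_condition_grid`). This matters because the pulse
model has a genuine strong-coupling pathology: when the frequency gap
between units exceeds what `K` can entrain (or at dyadic coupling `K/N = 4`,
where a single pulse can transiently exceed `omega_i`), a unit can be
trapped near the firing phase and drastically slowed. Such units did not
perform the task and their "variability" is uninterpretable. The exclusion
rate grows with `N` (≈ 0% of dyad units, ≈ 6% of octet units in our runs).

### What the model does and does not reproduce

With these conventions and the default parameters, the simulated grid
reproduces two of the three qualitative orderings of the empirical
variability pattern:

* the mean-field (aggregate) CoV is below the ensemble individuals' CoV at
  every group size;
* the individual-minus-mean-field gap increases monotonically with group
  size (the collective benefit grows with `N`);
* the pseudo-ensemble control — the mean field of *uncoupled* runs — is
  5–10 times more variable than the true ensemble mean field.

It does **not** reproduce the third ordering of the behavioral pattern:
human ensemble performers are *more* variable than solo performers, while
the model's coupled units are not.
In this implementation the pulse coupling acts as a continuous within-cycle
correction (the strong gamma pulse transiently pins a receiver's phase at
the firing phase), which *absorbs* part of each unit's own phase noise:
locked units inherit the steadier group timing and end up slightly *less*
variable than solo rotators. Producing excess individual variability under
coupling would require corrections that overshoot — discrete, weaker kicks
rather than saturating pulses — i.e. a pulse normalization different from
the unit-area gamma density integrated here. We keep the equations as defined
above and report the discrepancy rather than re-normalizing the pulse to
force the pattern; the corresponding acceptance test flags exactly this
sub-ordering.

## The analysis pipeline

The behavioral pipeline (`run_behavioral_pipeline`) mirrors standard
sensorimotor-synchronization practice and enforces a fixed order:

1. **Continuation extraction** (`split_phases`): only onsets after the paced
   phase are analyzed (full trial for synchronization-only tasks).
2. **Aggregate construction** (`aggregate_onsets`): pooled onsets are
   convolved with a Gaussian kernel (SD 50 ms, truncated at ±2 SD — we read
   the conventional "200 ms width" as total support, since an SD that large
   would merge adjacent beats at fast tempos; the SD is configurable),
   smoothed with a centered moving average of a quarter of the stimulus
   interval, and peak-picked with a minimum separation of half the stimulus
   interval, an amplitude floor of 10% of a single onset's peak (to ignore
   numerical ripples while still detecting genuine single-event clusters),
   and parabolic refinement on the default 1 kHz grid. Solo trials get the
   identical computation as a *pseudo-aggregate* baseline.
3. **IOI metrics** (`to_iois`, `remove_outlier_iois`, `tempo_trend`,
   `detrend_iois`, `prewhiten_iois`, `coefficient_of_variation`): intervals
   deviating more than 50% from the trial median are removed; the tempo
   trend is the OLS slope of tempo (60/IOI) on beat index (the printed
   regression convention; an IOI-slope variant is trivial to compute from
   the same series); variability is the SD of detrended, AR-prewhitened
   residuals divided by the raw mean interval (the residuals are near zero
   mean, so the denominator must come from the raw series). Pre-whitening
   fits each series' own AR model with AIC order selection up to
   `min(10, n/5)`; detrending precedes whitening.
4. **Alignment** (`align_iois`): onsets are matched to aggregate beat slots
   by temporal adjacency within half the aggregate's median interval; a beat
   slot contributes a row only when every performer has exactly one matched
   onset at both interval endpoints, so one skipped beat drops the two
   flanking intervals for everyone.
5. **Correlation profiles** (`autocorrelation`, `cross_correlation`,
   `acf_range`): biased (1/n) normalization, the convention of the standard
   R estimators used underneath; the ACF range statistic is the mean
   absolute successive-lag difference up to lag 8; cross-correlations use
   lags 0–4 with the convention that a positive lag means the first series
   follows the second.
6. **Transfer entropy and networks** (`bin_events`, `max_te`, `te_graph`,
   `causal_density`, `mean_node_strength`): onsets are binarized in 10 ms
   bins; the plug-in TE conditions on one past bin of the target exactly as
   in the defining formula, is maximized over delays of 1–100 bins (ties to
   the smallest delay), and is reported without bias correction or
   surrogate subtraction (a shuffle surrogate is available as a diagnostic
   only). Causal density is the mean directed edge weight; mean node
   strength is the mean outbound strength, equal to `(N-1)` times the
   density by construction — which is why strength rises with group size
   while density falls. An optional pre-binning linear rescaling of onset
   times (making the first and last interval match) is provided for
   trend-sensitivity checks, off by default.

## The synthetic tapper

`generate_trial` provides ground truth the oscillator model cannot: a
first-order error-correcting tapper with exactly known interval mean,
Gaussian clock noise, linear tempo drift, and miss/extra-hit rates. Jitter
perturbs the produced *interval* (clock noise), so an uncoupled tapper's
interval CoV is exactly `jitter_sd_s / base_ioi_s`; drift enters tempo
linearly so the trend slope is recovered to numerical precision on
noise-free input. With a correction gain in `(0, 2)` each tapper cancels a
fraction of its asynchrony to the previous group-mean onset, the minimal
mechanism producing the empirical alternation signature: negative lag-1
autocorrelation and negative lag-0 / positive lag-1 cross-correlation.
Gains of 2 or more are unstable and rejected. Notably, the pulse-coupled
oscillator dyads do *not* show the negative lag-0 signature (their
continuous mutual pinning makes intervals co-vary positively); the tapper is
therefore the generator of record for that regime, and is a test fixture,
not a scientific claim about mechanism.

## What the generators do and do not emulate

The simulators emulate quasi-periodic onset trains near 2 Hz with phase
noise, coupling-dependent co-variation, missed/extra events (via the tapper)
and solo controls. They do not emulate: expressive or metrically structured
timing, tempo-dependent motor noise, auditory-motor feedback delays, or
visual coupling. Passing tests on these generators therefore validates the
*pipeline arithmetic* and the *model's qualitative behavior*, not claims
about human data.

## Numerical choices and degenerate inputs

* Solver: fixed-step explicit RK3; noise added to the phase after the
  deterministic step; pulse forcing tabulated on a half-step grid so all RK3
  stages read consistent values; pulse contributions truncated 1 s after
  firing (the kernel is numerically zero there).
* Zero crossings: linear interpolation between bracketing samples; a
  refractory of half the unit's nominal period suppresses noise-induced
  double crossings (one onset per cycle).
* Mean-field onsets: crossings of `Psi` are discarded while coherence
  `r < 0.05` (configurable), where the mean-field phase is undefined.
* Seeding: one base seed spawns independent per-run seeds via R's RNG, so
  grids are reproducible and order-independent; identical configs give
  bit-identical onset trains.
* Degenerate inputs: empty trains round-trip through I/O; constant interval
  series return centered zeros from pre-whitening with a warning; series
  with fewer than 10 valid intervals skip whitening with a warning;
  explosive AR fits fall back to order 0.

## Problem sizes

The packaged studies use 20 runs per condition of 100 s at 300 Hz for the
grid, 10–20 seeded trials for stochastic assertions, 10^4 bins for the TE
analytic cases, and 100 replicates for recovery checks. These sizes give
stable orderings (stochastic assertions are made on means over runs) while
keeping any single check in the seconds-to-a-minute range.

## A small worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_oscillators = 4, coupling_strength = 8,
                  duration_s = 60, rng_seed = 1)
sim <- simulate_pulse_coupled(cfg)
mean(order_parameter(sim$trajectory$phases)$coherence)

trial <- trial_ensemble(sim$onsets, trial_id = "demo",
                        stimulus_tempo_bpm = 120,
                        condition = "ensemble", task = "synchronization_only")
res <- run_behavioral_pipeline(trial)
res$performer_metrics[, c("performer_id", "source", "cov",
                          "tempo_slope_bpm_per_beat")]
res$network_metrics
```

## Known limitations

* The strong-coupling pulse regime can suppress units with large frequency
  gaps (documented above); condition summaries exclude such units as
  missing observations.
* The ensemble-individuals-above-solo ordering of the behavioral data is
  not reproduced by these model equations under any noise discretization we
  tested; see the model-fidelity discussion above.
* The TE estimator is plug-in and biased upward at short series; only
  contrasts at matched lengths (e.g. coupled vs solo) should be
  interpreted, not absolute bit values.
* Mixed-effects inference on the resulting tables is deliberately out of
  scope; the package emits tidy tables for external statistical tooling.
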