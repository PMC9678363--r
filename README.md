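# groupsync

Simulation and analysis of collective timing in drumming ensembles.

When a group performs a synchronization–continuation task (drum with a
metronome, keep going after it stops), the ensemble as a whole can keep time
more steadily than any of its members — a temporal "wisdom of crowds". This
package is for researchers in sensorimotor synchronization and collective
dynamics who want to (a) simulate that phenomenon with coupled
phase-oscillator models and (b) run the complete descriptive pipeline on
onset-time data, real or simulated.

## What's inside

**Models.** Three Kuramoto-family simulators with a fixed-step third-order
Runge–Kutta solver:

- classic pairwise coupling
  `dθᵢ/dt = ωᵢ + (K/N) Σⱼ sin(θⱼ − θᵢ)` (`simulate_classic`);
- the algebraically equivalent mean-field form
  `dθᵢ/dt = ωᵢ + r K sin(Ψ − θᵢ)` with order parameter
  `r e^{iΨ} = mean(e^{iθⱼ})` (`simulate_meanfield`), used as the
  equivalence oracle of the classic form;
- a hybrid continuous–discrete pulse-coupled model
  (`simulate_pulse_coupled`): each oscillator emits a gamma-shaped pulse
  (unit-area density, shape 1.25, scale 0.02 s) at every upward zero-phase
  crossing, and receivers integrate
  `dθᵢ/dt = ωᵢ + (K/N) Σⱼ Pⱼ(t) · s · sin(θᵢ) + noise` on full, ring or
  uncoupled topologies. Onset trains are the interpolated zero crossings;
  the mean field's own crossings give the model analogue of the group
  aggregate.

**Pipeline.** Group-aggregate onsets by Gaussian-kernel smoothing and peak
picking (with a pseudo-aggregate control for solo data); inter-onset-interval
series with median-relative outlier removal, OLS tempo trend, detrending,
AR pre-whitening (AIC order selection) and coefficient of variation;
auto-/cross-correlation profiles and the ACF-range statistic;
point-process transfer entropy on 10-ms binned events, maximized over 1–100
bin delays; directed-network summaries (causal density, mean node strength).
`run_condition_grid` / `run_model_study` orchestrate the full model study;
`run_behavioral_pipeline` runs the analysis chain on any set of trials. A
synthetic error-correcting tapper (`generate_trial`) supplies ground truth
for pipeline validation.

## A worked example

Simulate a coupled quartet, wrap it as a trial, and run the full pipeline:

```r
library(groupsync)

cfg <- sim_config(n_oscillators = 4, coupling_strength = 8,
                  duration_s = 60, rng_seed = 1)
sim <- simulate_pulse_coupled(cfg)
mean(order_parameter(sim$trajectory$phases)$coherence)
#> [1] 0.84

trial <- trial_ensemble(sim$onsets, trial_id = "demo",
                        stimulus_tempo_bpm = 120,
                        condition = "ensemble", task = "synchronization_only")
res <- run_behavioral_pipeline(trial)
res$performer_metrics[, c("performer_id", "source", "n_onsets", "cov",
                          "tempo_slope_bpm_per_beat")]
#>      performer_id     source n_onsets    cov tempo_slope_bpm_per_beat
#> osc1         osc1 oscillator      124 0.0234                  0.00274
#> osc2         osc2 oscillator      125 0.0257                 -0.02055
#> osc3         osc3 oscillator      124 0.0204                  0.00213
#> osc4         osc4 oscillator      125 0.0250                  0.00377
#> 1       aggregate  aggregate      126 0.0226                 -0.06744

res$network_metrics
#>   trial_id group_size causal_density mean_node_strength
#> 1     demo          4         0.0313             0.0938
```

The quartet locks to a common beat (mean coherence 0.84), each oscillator's
processed interval CoV sits near 2–3%, the kernel-smoothed aggregate recovers
one beat per cycle, and the transfer-entropy graph yields a causal density
of 0.031 bits with mean node strength exactly `(N−1)` times that.

The methods vignette (`vignettes/group-synchronization-methods.Rmd`)
documents the models, the noise and sign conventions, every pipeline
parameter, and known limitations — including which orderings of the
empirical variability pattern the model equations do and do not reproduce.

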