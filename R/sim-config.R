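#' Configuration of a Kuramoto-variant simulation run
#'
#' Collects every parameter of a phase-oscillator simulation: ensemble size,
#' coupling strength and form, the distribution of intrinsic frequencies,
#' phase noise, pulse-kernel shape, solver rate and trial duration.
#'
#' The pulse-coupled variant drives each oscillator with the superposition of
#' gamma-shaped pulses emitted by the others at their zero-phase crossings
#' (one pulse per cycle). `pulse_sign` selects the sign of the `sin(theta_i)`
#' sensitivity term: the default `-1` is the phase-attracting convention under
#' which a pulse received near an oscillator's own firing phase pulls it
#' toward firing together, which is the configuration that produces group
#' synchronization (growing coherence). `+1` is the repelling convention.
#'
#' `noise_mode` selects how the Gaussian phase-rate noise `N(0, sigma)` is
#' discretized: `"per_sample"` treats sigma as the standard deviation of an
#' intrinsic-frequency fluctuation held over one solver step (phase increment
#' `sigma * dt` per step), the interpretation whose cycle-duration
#' variability at the default 300 Hz matches the behavioral scale;
#' `"sqrt_dt"` is the Euler-Maruyama diffusion discretization (increment
#' `sigma * sqrt(dt)`), invariant to the solver rate.
#'
#' @param n_oscillators ensemble size N (>= 1).
#' @param coupling_strength coupling gain K (dimensionless); 0 for solo.
#' @param freq_mean_hz,freq_sd_hz mean and SD of the Gaussian distribution of
#'   intrinsic frequencies, in Hz. Internally converted to rad/s.
#' @param noise_sigma SD of additive Gaussian phase-rate noise (rad/s under
#'   `"per_sample"`).
#' @param pulse_shape_a,pulse_scale_b_s gamma pulse shape and scale (s).
#' @param sample_rate_hz fixed solver step rate (Hz).
#' @param duration_s trial length (s).
#' @param topology `"full"`, `"ring"` (nearest neighbors, periodic boundary,
#'   requires N >= 3) or `"uncoupled"`.
#' @param coupling_form `"pulse"` (event-based gamma-pulse feedback) or
#'   `"continuous_difference"` (classic phase-difference coupling).
#' @param rng_seed integer seed controlling frequency draws, initial phases
#'   and noise.
#' @param noise_mode `"per_sample"` or `"sqrt_dt"` (see Details).
#' @param pulse_sign -1 (attracting, default) or +1 (as-printed repelling).
#' @param r_min coherence floor below which mean-field onsets are discarded.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_oscillators,
                       coupling_strength,
                       freq_mean_hz = 2,
                       freq_sd_hz = 0.5,
                       noise_sigma = 6,
                       pulse_shape_a = 1.25,
                       pulse_scale_b_s = 0.02,
                       sample_rate_hz = 300,
                       duration_s = 100,
                       topology = c("full", "ring", "uncoupled"),
                       coupling_form = c("pulse", "continuous_difference"),
                       rng_seed = 1L,
                       noise_mode = c("per_sample", "sqrt_dt"),
                       pulse_sign = -1,
                       r_min = 0.05) {
  topology <- match.arg(topology)
  coupling_form <- match.arg(coupling_form)
  noise_mode <- match.arg(noise_mode)
  stopifnot(n_oscillators >= 1,
            sample_rate_hz > 0,
            duration_s > 0,
            pulse_shape_a > 0,
            pulse_scale_b_s > 0,
            freq_sd_hz >= 0,
            noise_sigma >= 0,
            coupling_strength >= 0,
            pulse_sign %in% c(-1, 1),
            r_min >= 0, r_min < 1)
  if (topology == "ring" && n_oscillators < 3) {
    stop("ring topology requires N >= 3 (two distinct neighbors per unit)")
  }
  structure(list(n_oscillators = as.integer(n_oscillators),
                 coupling_strength = coupling_strength,
                 freq_mean_hz = freq_mean_hz,
                 freq_sd_hz = freq_sd_hz,
                 noise_sigma = noise_sigma,
                 pulse_shape_a = pulse_shape_a,
                 pulse_scale_b_s = pulse_scale_b_s,
                 sample_rate_hz = sample_rate_hz,
                 duration_s = duration_s,
                 topology = topology,
                 coupling_form = coupling_form,
                 rng_seed = as.integer(rng_seed),
                 noise_mode = noise_mode,
                 pulse_sign = pulse_sign,
                 r_min = r_min),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> N=%d K=%g %s/%s, omega ~ N(%g, %g) Hz, ",
                     "sigma=%g (%s), %g Hz solver, %g s, seed %d\n"),
              x$n_oscillators, x$coupling_strength, x$coupling_form,
              x$topology, x$freq_mean_hz, x$freq_sd_hz, x$noise_sigma,
              x$noise_mode, x$sample_rate_hz, x$duration_s, x$rng_seed))
  invisible(x)
}

#' Phase trajectory of a simulation run
#'
#' Internal constructor for the sampled phase output of an integrator.
#' `phases` is an N x T matrix of wrapped phases in `[0, 2*pi)`; `times` the
#' uniform sample grid.
#'
#' @keywords internal
phase_trajectory <- function(times, phases, natural_freqs_hz, config) {
  stopifnot(is.matrix(phases), ncol(phases) == length(times))
  structure(list(times = times,
                 phases = phases,
                 natural_freqs_hz = natural_freqs_hz,
                 config = config),
            class = "phase_trajectory")
}

#' @export
print.phase_trajectory <- function(x, ...) {
  cat(sprintf("<phase_trajectory> N=%d, %d samples over %.2f s (%g Hz)\n",
              nrow(x$phases), length(x$times), max(x$times),
              x$config$sample_rate_hz))
  invisible(x)
}
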