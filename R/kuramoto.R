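#' Gamma pulse kernel
#'
#' The stereotyped coupling pulse emitted at each zero-phase crossing: a
#' unit-area gamma density that rises sharply at time zero and decays over
#' roughly 200 ms at the default shape `a = 1.25`, scale `b = 0.02` s,
#' mimicking the acoustic envelope of a drum hit.
#'
#' @param t_since_fire time since the emitting oscillator fired (s), >= 0.
#' @param shape_a gamma shape parameter (> 0).
#' @param scale_b_s gamma scale parameter in seconds (> 0).
#' @return pulse amplitude `f(t | a, b) = t^(a-1) exp(-t/b) / (b^a Gamma(a))`.
#' @export
#' @examples
#' pulse_kernel(0.005, 1.25, 0.02)  # the kernel mode, (a-1)*b
pulse_kernel <- function(t_since_fire, shape_a = 1.25, scale_b_s = 0.02) {
  stopifnot(shape_a > 0, scale_b_s > 0)
  if (any(t_since_fire < 0)) stop("pulses are causal: t_since_fire must be >= 0")
  stats::dgamma(t_since_fire, shape = shape_a, scale = scale_b_s)
}

#' Mean-field order parameter
#'
#' The complex average of unit phasors: `r e^(i Psi) = mean(e^(i theta_j))`.
#' `r` is the coherence in \[0, 1\] and `Psi` the mean-field phase.
#'
#' @param phases numeric vector of N phases (radians), or an N x T matrix
#'   (one column per time sample).
#' @return list with `coherence` and `mean_phase` (scalars for a vector
#'   input, length-T vectors for a matrix).
#' @export
#' @examples
#' order_parameter(c(0, pi))           # antiphase: r = 0
#' order_parameter(c(1, 1, 1))$coherence  # identical phases: r = 1
order_parameter <- function(phases) {
  if (!length(phases)) stop("order_parameter needs at least one phase")
  if (is.matrix(phases)) {
    z <- colMeans(exp(1i * phases))
  } else {
    z <- mean(exp(1i * phases))
  }
  list(coherence = Mod(z), mean_phase = Arg(z))
}

## shared setup: draw frequencies and initial phases under the config seed,
## then hand off to a compiled integrator. Frequencies are drawn in Hz and
## converted to rad/s; initial phases are uniform on [0, 2*pi).
sim_setup <- function(config) {
  set.seed(config$rng_seed)
  freqs_hz <- stats::rnorm(config$n_oscillators,
                           config$freq_mean_hz, config$freq_sd_hz)
  theta0 <- stats::runif(config$n_oscillators, 0, 2 * pi)
  dt <- 1 / config$sample_rate_hz
  nstep <- round(config$duration_s * config$sample_rate_hz)
  noise_sd_step <- switch(config$noise_mode,
                          per_sample = config$noise_sigma * dt,
                          sqrt_dt    = config$noise_sigma * sqrt(dt))
  list(freqs_hz = freqs_hz, omega_rad = 2 * pi * freqs_hz, theta0 = theta0,
       dt = dt, nstep = nstep, noise_sd_step = noise_sd_step)
}

#' Simulate the classic Kuramoto model
#'
#' Integrates `dtheta_i/dt = omega_i + (K/N) sum_j sin(theta_j - theta_i)`
#' plus optional phase noise, with a fixed-step third-order Runge-Kutta
#' solver.
#'
#' @param config a [sim_config] with `coupling_form = "continuous_difference"`.
#' @return A `phase_trajectory`.
#' @export
simulate_classic <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$coupling_form != "continuous_difference") {
    stop("simulate_classic requires coupling_form = 'continuous_difference'")
  }
  if (config$topology == "ring") {
    stop("the continuous-coupling variant is defined on the full topology")
  }
  s <- sim_setup(config)
  K <- if (config$topology == "uncoupled") 0 else config$coupling_strength
  out <- .kuramoto_continuous(s$omega_rad, s$theta0, K, s$dt, s$nstep,
                              0L, s$noise_sd_step)
  phase_trajectory(seq(0, by = s$dt, length.out = s$nstep + 1),
                   out$phases, s$freqs_hz, config)
}

#' Simulate the mean-field form of the Kuramoto model
#'
#' Integrates `dtheta_i/dt = omega_i + r K sin(Psi - theta_i)` with the
#' order parameter `(r, Psi)` recomputed from the current phases at every
#' solver stage. Algebraically identical to [simulate_classic()]; serves as
#' its equivalence oracle.
#'
#' @inheritParams simulate_classic
#' @return A `phase_trajectory`.
#' @export
simulate_meanfield <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$coupling_form != "continuous_difference") {
    stop("simulate_meanfield requires coupling_form = 'continuous_difference'")
  }
  if (config$topology == "ring") {
    stop("the mean-field form is defined on the full topology")
  }
  s <- sim_setup(config)
  K <- if (config$topology == "uncoupled") 0 else config$coupling_strength
  out <- .kuramoto_continuous(s$omega_rad, s$theta0, K, s$dt, s$nstep,
                              1L, s$noise_sd_step)
  phase_trajectory(seq(0, by = s$dt, length.out = s$nstep + 1),
                   out$phases, s$freqs_hz, config)
}

#' Simulate the hybrid pulse-coupled model
#'
#' The event-based variant: each oscillator emits a gamma-shaped pulse once
#' per cycle when its phase crosses zero, and is driven by the superposition
#' of the pulses of its coupling partners through a `sin(theta_i)`
#' sensitivity term (see [sim_config] for the sign convention). Supports the
#' full, ring (nearest-neighbor, periodic boundary) and uncoupled
#' topologies.
#'
#' @param config a [sim_config] with `coupling_form = "pulse"`.
#' @return list with `trajectory` (a `phase_trajectory`) and `onsets` (a
#'   list of [onset_train] objects, one per oscillator, holding the upward
#'   zero-crossing times).
#' @export
simulate_pulse_coupled <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$coupling_form != "pulse") {
    stop("simulate_pulse_coupled requires coupling_form = 'pulse'")
  }
  if (config$duration_s < 1 / config$freq_mean_hz) {
    stop("duration shorter than one mean period")
  }
  s <- sim_setup(config)
  topo <- match(config$topology, c("full", "ring", "uncoupled")) - 1L
  out <- .kuramoto_pulse(s$omega_rad, s$theta0, config$coupling_strength,
                         s$dt, s$nstep, topo, s$noise_sd_step,
                         config$pulse_shape_a, config$pulse_scale_b_s,
                         config$pulse_sign, kernel_support_s = 1)
  trains <- lapply(seq_len(config$n_oscillators), function(i) {
    onset_train(out$onsets[[i]], performer_id = paste0("osc", i),
                source = "oscillator")
  })
  traj <- phase_trajectory(seq(0, by = s$dt, length.out = s$nstep + 1),
                           out$phases, s$freqs_hz, config)
  list(trajectory = traj, onsets = trains)
}

#' Extract onsets from a phase trajectory
#'
#' Returns the times at which an oscillator's phase crosses zero upward
#' (through the wrap), linearly interpolated between the bracketing samples.
#' A refractory of half the oscillator's nominal period suppresses
#' noise-induced double crossings, giving one onset per cycle.
#'
#' @param trajectory a `phase_trajectory`.
#' @param oscillator_index which oscillator row to use.
#' @return An [onset_train] (possibly empty).
#' @export
extract_onsets <- function(trajectory, oscillator_index = 1) {
  stopifnot(inherits(trajectory, "phase_trajectory"))
  th_w <- trajectory$phases[oscillator_index, ]
  dt <- 1 / trajectory$config$sample_rate_hz
  ## unwrap assuming less than half a cycle of motion per sample
  d <- diff(th_w)
  d <- d - 2 * pi * round(d / (2 * pi))
  th <- cumsum(c(th_w[1], d))
  f_hz <- trajectory$natural_freqs_hz[oscillator_index]
  refrac <- if (is.finite(f_hz) && abs(f_hz) > 0) 0.5 / abs(f_hz) else 0
  crossing_times(th, trajectory$times, refrac)
}

## upward crossings of multiples of 2*pi of an unwrapped series
crossing_times <- function(th, times, refractory_s) {
  n <- length(th)
  lev0 <- floor(th / (2 * pi))
  idx <- which(diff(lev0) >= 1 & diff(th) > 0)
  out <- numeric(0)
  last <- -Inf
  for (k in idx) {
    tgt <- 2 * pi * (lev0[k] + 1)
    frac <- (tgt - th[k]) / (th[k + 1] - th[k])
    tc <- times[k] + frac * (times[k + 1] - times[k])
    if (tc - last >= refractory_s) {
      out <- c(out, tc)
      last <- tc
    }
  }
  onset_train(out, performer_id = "unit", source = "oscillator")
}

#' Onsets of the mean field
#'
#' Zero crossings of the mean-field phase `Psi(t)`, computed like
#' [extract_onsets()]. Crossings while the coherence is below `r_min` are
#' discarded: when `r` is near zero the mean-field phase is undefined and
#' its crossings are spurious.
#'
#' @param trajectory a `phase_trajectory` with N >= 2 oscillators.
#' @param r_min coherence floor (defaults to the config's `r_min`).
#' @return An [onset_train] with source `"mean_field"`.
#' @export
mean_field_onsets <- function(trajectory, r_min = NULL) {
  stopifnot(inherits(trajectory, "phase_trajectory"))
  if (nrow(trajectory$phases) < 2) stop("mean field requires N >= 2")
  if (is.null(r_min)) r_min <- trajectory$config$r_min
  op <- order_parameter(trajectory$phases)
  psi_w <- op$mean_phase
  d <- diff(psi_w)
  d <- d - 2 * pi * round(d / (2 * pi))
  psi <- cumsum(c(psi_w[1], d))
  refrac <- 0.5 / trajectory$config$freq_mean_hz
  tr <- crossing_times(psi, trajectory$times, refrac)
  ## drop crossings that occur while the mean field is degenerate
  if (length(tr)) {
    r_at <- stats::approx(trajectory$times, op$coherence, xout = unclass(tr))$y
    tr <- tr[r_at >= r_min]
  }
  onset_train(unclass(tr), performer_id = "mean_field", source = "mean_field")
}
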