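test_that("pulse kernel is the unit-area gamma density with the closed-form mode", {
  ## vanishes at t = 0+ since shape > 1 (slowly, as t^(a-1) with a-1 = 0.25)
  tt0 <- 10^seq(-20, -4, by = 2)
  expect_true(all(diff(pulse_kernel(tt0, 1.25, 0.02)) > 0))
  expect_lt(pulse_kernel(1e-20, 1.25, 0.02), 1e-2)
  expect_equal(pulse_kernel(0, 1.25, 0.02), 0)

  ## mode at (a-1)*b, cross-checked by dense grid search
  tt <- seq(1e-5, 0.1, by = 1e-5)
  grid_mode <- tt[which.max(pulse_kernel(tt, 1.25, 0.02))]
  expect_equal(grid_mode, (1.25 - 1) * 0.02, tolerance = 1e-3)

  ## integrates to 1 over [0, 1 s] (quadrature oracle; tail beyond 1 s nil)
  q <- stats::integrate(pulse_kernel, 0, 1, shape_a = 1.25,
                        scale_b_s = 0.02, rel.tol = 1e-10)
  expect_equal(q$value, 1, tolerance = 1e-6)

  expect_error(pulse_kernel(-0.01), "causal")
})

test_that("order parameter matches the direct complex mean and cancels symmetric phases", {
  expect_equal(order_parameter(rep(1.3, 5))$coherence, 1)
  expect_equal(order_parameter(c(0, pi))$coherence, 0, tolerance = 1e-12)
  ## four-phase cancellation, verified against the direct phasor sum
  ph <- c(0, pi / 2, pi, 3 * pi / 2)
  direct <- Mod(mean(exp(1i * ph)))
  expect_equal(order_parameter(ph)$coherence, direct)
  expect_lt(direct, 1e-12)
  expect_error(order_parameter(numeric(0)))
  ## matrix input gives one value per column, all within [0, 1]
  m <- matrix(runif(30, 0, 2 * pi), 3, 10)
  op <- order_parameter(m)
  expect_length(op$coherence, 10)
  expect_true(all(op$coherence >= 0 & op$coherence <= 1))
})

test_that("classic and mean-field forms agree on random noise-free configs", {
  set.seed(42)
  for (k in 1:10) {
    cfg <- sim_config(n_oscillators = sample(2:16, 1),
                      coupling_strength = runif(1, 0, 10),
                      freq_mean_hz = runif(1, 1, 3),
                      freq_sd_hz = runif(1, 0, 0.6),
                      noise_sigma = 0,
                      duration_s = 20, sample_rate_hz = 200,
                      coupling_form = "continuous_difference",
                      rng_seed = 1000 + k)
    t1 <- simulate_classic(cfg)
    t2 <- simulate_meanfield(cfg)
    dphase <- abs(t1$phases - t2$phases)
    dphase <- pmin(dphase, 2 * pi - dphase)   # wrapped distance
    expect_lt(max(dphase), 1e-6)
  }
})

test_that("identical-frequency ensembles lock to high coherence", {
  cfg <- sim_config(8, 8, freq_sd_hz = 0, noise_sigma = 0, duration_s = 20,
                    coupling_form = "continuous_difference", rng_seed = 7)
  tr <- simulate_classic(cfg)
  r_end <- order_parameter(tr$phases[, ncol(tr$phases)])$coherence
  expect_gt(r_end, 0.99)
})

test_that("decoupled oscillators advance linearly at their natural frequencies", {
  cfg <- sim_config(5, 0, noise_sigma = 0, duration_s = 10,
                    coupling_form = "continuous_difference", rng_seed = 11)
  tr <- simulate_classic(cfg)
  for (i in 1:5) {
    d <- diff(tr$phases[i, ])
    d <- d - 2 * pi * round(d / (2 * pi))
    unwrapped <- cumsum(c(tr$phases[i, 1], d))
    slope <- (unwrapped[length(unwrapped)] - unwrapped[1]) / max(tr$times)
    expect_equal(slope, 2 * pi * tr$natural_freqs_hz[i], tolerance = 1e-6)
  }
})

test_that("single oscillator ignores coupling entirely", {
  c1 <- sim_config(1, 0, noise_sigma = 0, duration_s = 5,
                   coupling_form = "continuous_difference", rng_seed = 3)
  c2 <- sim_config(1, 9, noise_sigma = 0, duration_s = 5,
                   coupling_form = "continuous_difference", rng_seed = 3)
  expect_identical(simulate_classic(c1)$phases, simulate_classic(c2)$phases)
})

test_that("phase trajectories are wrapped and the time grid is uniform", {
  cfg <- sim_config(4, 8, duration_s = 5, rng_seed = 2)
  s <- simulate_pulse_coupled(cfg)
  expect_true(all(s$trajectory$phases >= 0 & s$trajectory$phases < 2 * pi))
  expect_equal(diff(s$trajectory$times),
               rep(1 / cfg$sample_rate_hz, length(s$trajectory$times) - 1))
  ## coherence stays within [0, 1] along the whole run
  r <- order_parameter(s$trajectory$phases)$coherence
  expect_true(all(r >= 0 & r <= 1 + 1e-12))
})

test_that("solo pulse oscillators fire exactly periodically without noise", {
  cfg <- sim_config(3, 0, noise_sigma = 0, duration_s = 20, rng_seed = 5)
  s <- simulate_pulse_coupled(cfg)
  for (i in 1:3) {
    d <- diff(as.numeric(s$onsets[[i]]))
    period <- 1 / s$trajectory$natural_freqs_hz[i]
    expect_true(all(abs(d - period) < 1 / cfg$sample_rate_hz))
  }
})

test_that("onset counts in the decoupled limit match the cycle count", {
  cfg <- sim_config(1, 0, freq_sd_hz = 0, noise_sigma = 0, duration_s = 100,
                    rng_seed = 1)
  s <- simulate_pulse_coupled(cfg)
  expect_true(length(s$onsets[[1]]) %in% c(199, 200))
})

test_that("extract_onsets interpolates crossings of a known rotator", {
  cfg <- sim_config(1, 0, freq_sd_hz = 0, noise_sigma = 0, duration_s = 10,
                    coupling_form = "continuous_difference", rng_seed = 1)
  tr <- simulate_classic(cfg)
  ## theta(0) is random; onsets are theta0-dependent but spacing is exact
  on <- extract_onsets(tr, 1)
  expect_equal(diff(as.numeric(on)), rep(0.5, length(on) - 1),
               tolerance = 1e-6)
  ## a frozen phase yields no onsets
  frozen <- sim_config(1, 0, freq_mean_hz = 0, freq_sd_hz = 0,
                       noise_sigma = 0, duration_s = 5,
                       coupling_form = "continuous_difference", rng_seed = 1)
  expect_length(extract_onsets(simulate_classic(frozen), 1), 0)
})

test_that("seed determinism gives bit-identical onset trains", {
  cfg <- sim_config(4, 8, duration_s = 20, rng_seed = 99)
  s1 <- simulate_pulse_coupled(cfg)
  s2 <- simulate_pulse_coupled(cfg)
  for (i in 1:4) expect_identical(as.numeric(s1$onsets[[i]]),
                                  as.numeric(s2$onsets[[i]]))
})

test_that("noise-free trajectories are robust to doubling the solver rate", {
  base <- sim_config(6, 8, noise_sigma = 0, duration_s = 10,
                     sample_rate_hz = 300,
                     coupling_form = "continuous_difference", rng_seed = 21)
  fine <- sim_config(6, 8, noise_sigma = 0, duration_s = 10,
                     sample_rate_hz = 600,
                     coupling_form = "continuous_difference", rng_seed = 21)
  t1 <- simulate_classic(base)
  t2 <- simulate_classic(fine)
  d <- abs(t1$phases[, ncol(t1$phases)] - t2$phases[, ncol(t2$phases)])
  d <- pmin(d, 2 * pi - d)
  expect_lt(max(d), 1e-4)
})

test_that("ring topology runs and returns one train per unit", {
  cfg <- sim_config(8, 8, topology = "ring", duration_s = 20, rng_seed = 13)
  s <- simulate_pulse_coupled(cfg)
  expect_length(s$onsets, 8)
  expect_true(all(vapply(s$onsets, length, 0L) > 0))
  expect_error(sim_config(2, 8, topology = "ring"), "N >= 3")
})

test_that("repelling pulse sign is available as a config switch", {
  cfg <- sim_config(4, 8, duration_s = 10, rng_seed = 3, pulse_sign = 1)
  s <- simulate_pulse_coupled(cfg)   # runs; no synchronization asserted
  expect_length(s$onsets, 4)
})

test_that("mean-field onsets track a locked ensemble and reject degenerate fields", {
  ## locked identical ensemble: mean-field train matches any individual's
  cfg <- sim_config(4, 8, freq_sd_hz = 0, noise_sigma = 0, duration_s = 20,
                    rng_seed = 31)
  s <- simulate_pulse_coupled(cfg)
  mf <- mean_field_onsets(s$trajectory)
  ind <- s$onsets[[1]]
  n <- min(length(mf), length(ind))
  expect_gt(n, 10)
  offs <- abs(as.numeric(mf)[seq_len(n)] - as.numeric(ind)[seq_len(n)])
  expect_lt(stats::median(offs), 0.5 / cfg$freq_mean_hz)

  ## exact antiphase dyad: r = 0 throughout, no crossings accepted
  ph <- matrix(c(seq(0, 4 * pi, length.out = 101),
                 seq(0, 4 * pi, length.out = 101) + pi), 2, byrow = TRUE)
  ph <- ph %% (2 * pi)
  traj <- structure(list(times = seq(0, 1, length.out = 101), phases = ph,
                         natural_freqs_hz = c(2, 2),
                         config = sim_config(2, 0, rng_seed = 1)),
                    class = "phase_trajectory")
  expect_length(mean_field_onsets(traj), 0)
})

test_that("ensemble coupling pulls cycle durations together across oscillators", {
  ## SD across oscillators of the mean cycle duration shrinks under coupling
  set.seed(1)
  gains <- vapply(1:20, function(k) {
    s <- simulate_pulse_coupled(sim_config(8, 8, duration_s = 50,
                                           rng_seed = 5000 + k))
    means <- vapply(s$onsets, function(tr) {
      tt <- as.numeric(tr)
      if (length(tt) < 10) NA_real_ else mean(diff(tt))
    }, 0)
    freqs <- s$trajectory$natural_freqs_hz
    if (anyNA(means)) NA else sd(means) < sd(1 / freqs)
  }, TRUE)
  expect_gt(mean(gains, na.rm = TRUE), 0.8)
})

test_that("mean-field cycles are steadier than individual cycles in locked ensembles", {
  set.seed(2)
  wins <- vapply(1:20, function(k) {
    s <- simulate_pulse_coupled(sim_config(8, 8, duration_s = 50,
                                           rng_seed = 6000 + k))
    mf <- mean_field_onsets(s$trajectory)
    if (length(mf) < 10) return(NA)
    cv_of(mf) < mean(vapply(s$onsets, cv_of, 0))
  }, TRUE)
  expect_gt(mean(wins, na.rm = TRUE), 0.7)
})
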