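test_that("interval differencing and tempo conversion", {
  s <- to_iois(onset_train(c(0, 0.5, 1.0)))
  expect_equal(s$ioi_s, c(0.5, 0.5))
  expect_equal(s$tempo_bpm, c(120, 120))
  s2 <- to_iois(onset_train(c(0, 0.5, 1.5)))
  expect_equal(s2$ioi_s, c(0.5, 1.0))
  expect_error(to_iois(onset_train(1)), "at least 2")
})

test_that("median-relative outlier removal flags skipped beats", {
  s <- to_iois(onset_train(cumsum(c(0, 0.5, 0.5, 1.0, 0.5))))
  cleaned <- remove_outlier_iois(s)
  expect_equal(s$ioi_s[!cleaned$valid], 1.0)
  expect_equal(ioi_values(cleaned), c(0.5, 0.5, 0.5))

  ## 48% above median survives the 50% rule
  s48 <- to_iois(onset_train(cumsum(c(0, 0.5, 0.5, 0.74))))
  expect_true(all(remove_outlier_iois(s48)$valid))

  ## constant series untouched
  sc <- to_iois(periodic_train(n = 10))
  expect_true(all(remove_outlier_iois(sc)$valid))
})

test_that("tempo trend recovers exact linear tempo input", {
  expect_equal(tempo_trend(to_iois(periodic_train(n = 20))), 0,
               tolerance = 1e-12)
  ## construct T_n = 120 + 0.1 n exactly
  tempo <- 120 + 0.1 * (1:30)
  onsets <- cumsum(c(0, 60 / tempo))
  expect_equal(tempo_trend(to_iois(onset_train(onsets))), 0.1,
               tolerance = 1e-9)
  ## linearly shrinking intervals match a closed-form OLS fit of 60/IOI on n
  ioi <- seq(0.500, 0.480, length.out = 20)
  n <- seq_along(ioi)
  slope <- stats::cov(n, 60 / ioi) / stats::var(n)
  expect_equal(tempo_trend(to_iois(onset_train(cumsum(c(0, ioi))))), slope,
               tolerance = 1e-9)
  expect_error(tempo_trend(to_iois(onset_train(c(0, 1, 2))[1:2])), "at least")
})

test_that("time-reversing a linear tempo trial negates the trend", {
  ioi <- seq(0.500, 0.460, length.out = 25)
  fwd <- tempo_trend(to_iois(onset_train(cumsum(c(0, ioi)))))
  rev_ioi <- rev(ioi)
  bwd <- tempo_trend(to_iois(onset_train(cumsum(c(0, rev_ioi)))))
  expect_equal(bwd, -fwd, tolerance = 1e-9)
})

test_that("detrending removes a linear ramp and preserves the raw mean", {
  ramp <- to_iois(onset_train(cumsum(c(0, seq(0.4, 0.6, length.out = 30)))))
  d <- detrend_iois(ramp)
  expect_lt(max(abs(ioi_values(d))), 1e-12)
  expect_equal(d$raw_mean_ioi_s, mean(ramp$ioi_s))

  ## white-noise residual SD survives detrending up to the 2-dof OLS loss
  set.seed(4)
  y <- rnorm(200, 0.5, 0.02)
  s <- to_iois(onset_train(cumsum(c(0, y))))
  d2 <- detrend_iois(s)
  expect_equal(sd(ioi_values(d2)), sd(y), tolerance = 0.05)

  const <- detrend_iois(to_iois(periodic_train(n = 10)))
  expect_lt(max(abs(ioi_values(const))), 1e-12)
  expect_equal(const$raw_mean_ioi_s, 0.5)
})

test_that("AR prewhitening selects low order on white noise and whitens AR(1)", {
  set.seed(11)
  ## white noise: order 0 selected in the clear majority of series
  orders <- vapply(1:100, function(k) {
    y <- rnorm(120, 0.5, 0.02)
    s <- to_iois(onset_train(cumsum(c(0, y))))
    w <- prewhiten_iois(s)
    w$ar_order
  }, 0L)
  expect_gt(mean(orders == 0), 0.5)

  ## AR(1) with phi = 0.6: whitened lag-1 autocorrelation within 2/sqrt(n)
  hits <- vapply(1:100, function(k) {
    n <- 200
    e <- rnorm(n, 0, 0.01)
    y <- as.numeric(stats::filter(e, 0.6, method = "recursive")) + 0.5
    s <- to_iois(onset_train(cumsum(c(0, y))))
    w <- prewhiten_iois(s)
    v <- ioi_values(w)[-seq_len(max(w$ar_order, 1))]
    abs(stats::acf(v, plot = FALSE, lag.max = 1)$acf[2]) <= 2 / sqrt(length(v))
  }, TRUE)
  expect_gte(mean(hits), 0.9)

  ## constant series: centered zeros with a warning
  expect_warning(w0 <- prewhiten_iois(to_iois(periodic_train(n = 30))),
                 "zero-variance")
  expect_true(all(ioi_values(w0) == 0))

  ## short series returned unchanged with a warning
  expect_warning(ws <- prewhiten_iois(to_iois(onset_train(cumsum(c(0, runif(5, 0.4, 0.6)))))),
                 "fewer than 10")
})

test_that("coefficient of variation uses the raw-interval denominator and is scale-free", {
  s <- to_iois(onset_train(cumsum(c(0, rep(0.5, 50)))))
  s$ioi_s <- rnorm(50, 0, 0.01)          # stand-in processed residuals
  s$stage <- "prewhitened"
  expect_equal(coefficient_of_variation(s), sd(s$ioi_s) / 0.5)

  ## doubling all times leaves the pipeline CoV unchanged
  set.seed(8)
  y <- rnorm(100, 0.5, 0.015)
  t1 <- onset_train(cumsum(c(0, y)))
  t2 <- onset_train(2 * cumsum(c(0, y)))
  expect_equal(ioi_variability(t1)$cov, ioi_variability(t2)$cov,
               tolerance = 1e-10)
})

test_that("full variability pipeline is deterministic on simulator output", {
  s <- simulate_pulse_coupled(sim_config(1, 0, duration_s = 60, rng_seed = 77))
  v1 <- ioi_variability(s$onsets[[1]])
  s2 <- simulate_pulse_coupled(sim_config(1, 0, duration_s = 60, rng_seed = 77))
  v2 <- ioi_variability(s2$onsets[[1]])
  expect_identical(v1$cov, v2$cov)
  expect_gt(v1$cov, 0)
  expect_true(is.finite(v1$cov))
})

test_that("alignment pairs identical trains completely", {
  a <- periodic_train(n = 10, id = "a")
  b <- onset_train(as.numeric(a), performer_id = "b")
  agg <- aggregate_onsets(list(a, b), stimulus_ioi_s = 0.5)
  m <- align_iois(list(a, b), agg)
  expect_equal(nrow(m), 9)
  expect_equal(unname(m[, 1]), unname(m[, 2]))
})

test_that("a missed beat drops the two flanking intervals for everyone", {
  grid <- 0.5 * (1:12)
  a <- onset_train(grid, "a")
  b <- onset_train(grid[-6], "b")     # b skips beat 6
  agg <- aggregate_onsets(list(a, b), stimulus_ioi_s = 0.5)
  m <- align_iois(list(a, b), agg)
  expect_equal(nrow(m), length(grid) - 1 - 2)
  ## surviving intervals are all one beat long for both performers
  expect_true(all(abs(m - 0.5) < 1e-6))
})

test_that("moderate jitter keeps all rows and column order is respected", {
  trains <- jittered_ensemble(n_perf = 3, n_beats = 20, jitter_sd = 0.02,
                              seed = 5)
  agg <- aggregate_onsets(trains, stimulus_ioi_s = 0.5)
  m <- align_iois(trains, agg)
  expect_equal(nrow(m), 19)
  ## permuting performers permutes columns identically
  m2 <- align_iois(trains[c(3, 1, 2)], agg)
  expect_equal(matrix(m2, nrow(m2)), matrix(m[, c(3, 1, 2)], nrow(m)))
  expect_equal(colnames(m2), colnames(m)[c(3, 1, 2)])
})
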