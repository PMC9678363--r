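test_that("event binning is occupancy on the stated grid", {
  b <- bin_events(onset_train(c(0.005, 0.995)), 0.010, duration_s = 1)
  expect_length(b, 100)
  expect_equal(which(b == 1), c(1, 100))

  ## two onsets in one bin collapse to a single occupancy mark
  b2 <- bin_events(c(0.001, 0.002), 0.010, duration_s = 1)
  expect_equal(sum(b2), 1)

  expect_equal(sum(bin_events(numeric(0), 0.010, 1)), 0)
  expect_error(bin_events(c(0.5, 2), 0.010, duration_s = 1), "beyond")
})

## entropy oracle: H(X | Y) from a joint table of two binary streams
cond_entropy <- function(x1, x0) {
  tab <- table(factor(x1, c(0, 1)), factor(x0, c(0, 1)))
  p <- tab / sum(tab)
  h <- 0
  for (j in 1:2) {
    pj <- sum(p[, j])
    if (pj == 0) next
    for (i in 1:2) {
      if (p[i, j] == 0) next
      h <- h - p[i, j] * log2(p[i, j] / pj)
    }
  }
  h
}

test_that("transfer entropy is non-negative and vanishes for empty sources", {
  set.seed(51)
  for (k in 1:20) {
    src <- rbinom(500, 1, runif(1, 0.05, 0.5))
    tgt <- rbinom(500, 1, runif(1, 0.05, 0.5))
    expect_gte(transfer_entropy(src, tgt, sample(1:20, 1)), 0)
  }
  tgt <- rbinom(500, 1, 0.2)
  for (d in c(1, 5, 50)) {
    expect_equal(transfer_entropy(integer(500), tgt, d), 0)
  }
  expect_error(transfer_entropy(integer(10), integer(11), 1),
               "lengths differ")
})

test_that("a delayed copy attains the conditional-entropy ceiling at the true delay", {
  set.seed(61)
  n <- 10000
  d0 <- 7
  src <- rbinom(n, 1, 0.15)
  tgt <- c(integer(d0), src[1:(n - d0)])    # target = source delayed by d0
  te <- transfer_entropy(src, tgt, d0)
  ## oracle: TE at the true delay equals H(i_{t+1} | i_t) of the target,
  ## because the source determines i_{t+1} exactly
  t_idx <- d0:(n - 1)
  h <- cond_entropy(tgt[t_idx + 1], tgt[t_idx])
  expect_equal(te, h, tolerance = 1e-9)

  mt <- max_te(src, tgt, max_delay_bins = 30)
  expect_equal(mt$best_delay, d0)
  expect_equal(mt$te_bits, h, tolerance = 1e-9)
})

test_that("independent periodic trains carry almost no transfer entropy", {
  a <- bin_events(seq(0.1, 99, by = 0.47), 0.010, 100)
  b <- bin_events(seq(0.23, 99, by = 0.53), 0.010, 100)
  te <- max_te(a, b, max_delay_bins = 50)$te_bits
  expect_lt(te, 0.01)
})

test_that("max TE over a superset of delays dominates the subset maximum", {
  set.seed(71)
  src <- rbinom(3000, 1, 0.2)
  tgt <- rbinom(3000, 1, 0.2)
  m20 <- max_te(src, tgt, 20)$te_bits
  m60 <- max_te(src, tgt, 60)$te_bits
  expect_gte(m60, m20)
})

test_that("TE graphs have N(N-1) edges and relabel consistently", {
  set.seed(81)
  trains <- lapply(1:4, function(p)
    onset_train(sort(runif(60, 0, 30)), performer_id = paste0("p", p)))
  g <- te_graph(trains, max_delay_bins = 20, duration_s = 30)
  expect_equal(dim(g$weights), c(4, 4))
  expect_true(all(diag(g$weights) == 0))
  expect_equal(sum(g$weights > 0 | g$weights == 0) - 4, 12)  # 12 off-diagonal

  ## permuting performers permutes the weight matrix
  perm <- c(3, 1, 4, 2)
  g2 <- te_graph(trains[perm], max_delay_bins = 20, duration_s = 30)
  expect_equal(unname(g2$weights), unname(g$weights[perm, perm]))

  two <- te_graph(trains[1:2], max_delay_bins = 20, duration_s = 30)
  expect_equal(sum(two$weights != 0 | two$weights == 0) - 2, 2)
})

test_that("causal density and node strength honor their defining identity", {
  mk_graph <- function(w) {
    n <- nrow(w); diag(w) <- 0
    ids <- paste0("p", seq_len(n))
    dimnames(w) <- list(ids, ids)
    structure(list(nodes = ids, weights = w,
                   best_delay = matrix(1, n, n)), class = "te_graph")
  }
  g <- mk_graph(matrix(0.3, 5, 5))
  expect_equal(causal_density(g), 0.3)
  expect_equal(mean_node_strength(g), 4 * 0.3)

  gd <- mk_graph(matrix(c(0, 0.2, 0.4, 0), 2, 2, byrow = TRUE))
  expect_equal(causal_density(gd), 0.3)
  expect_equal(mean_node_strength(gd), 0.3)

  ## identity strength = (N-1) * density on random graphs
  set.seed(91)
  for (k in 1:100) {
    n <- sample(2:8, 1)
    g <- mk_graph(matrix(runif(n * n), n, n))
    expect_equal(mean_node_strength(g), (n - 1) * causal_density(g),
                 tolerance = 1e-12)
  }
  ## density invariant under relabeling
  w <- matrix(runif(16), 4, 4)
  perm <- c(2, 4, 1, 3)
  expect_equal(causal_density(mk_graph(w)),
               causal_density(mk_graph(w[perm, perm])))
})

test_that("ensemble coupling raises transfer entropy above the solo baseline", {
  dens <- function(K, seed) {
    s <- simulate_pulse_coupled(sim_config(4, K, duration_s = 50,
                                           rng_seed = seed))
    causal_density(te_graph(s$onsets, max_delay_bins = 100, duration_s = 50))
  }
  d8 <- vapply(1:10, function(k) dens(8, 300 + k), 0)
  d0 <- vapply(1:10, function(k) dens(0, 400 + k), 0)
  expect_gt(mean(d8), mean(d0))
})

test_that("shuffle surrogates sit below a strongly coupled pair's TE", {
  s <- simulate_pulse_coupled(sim_config(2, 8, duration_s = 60, rng_seed = 17))
  obs <- max_te(bin_events(s$onsets[[1]], 0.010, 60),
                bin_events(s$onsets[[2]], 0.010, 60), 100)$te_bits
  set.seed(5)
  sur <- te_shuffle_surrogate(s$onsets[[1]], s$onsets[[2]], duration_s = 60,
                              n_surrogates = 10)
  expect_gt(obs, stats::quantile(sur, 0.9))
})
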