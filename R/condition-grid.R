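#' Run a grid of simulation conditions
#'
#' Runs the pulse-coupled (or variant) simulator over the full crossing of
#' group sizes and coupling strengths, with independent seeded substreams
#' per run, and tabulates per-run cycle-duration variability for every
#' oscillator and for the mean field.
#'
#' Two CoV columns are reported per unit: `cov_raw` on all cycle durations,
#' and `cov_clean` after removing durations deviating more than 50% from
#' the unit's median (the interval-level outlier rule used throughout the
#' behavioral pipeline, which strips the doubled/halved durations produced
#' by occasional missed or spurious crossings). `valid` flags units whose
#' onset count lies within 50% of the count expected from their intrinsic
#' frequency (nominal frequency for the mean field): trains failing this
#' performed so little of the task that their variability is not
#' interpretable, and summaries treat them as missing observations.
#'
#' @param group_sizes integer vector of ensemble sizes (default `c(2, 4, 8)`).
#' @param coupling numeric vector of coupling strengths (default `c(0, 8)`;
#'   0 is labelled `"solo"`, positive values `"ensemble"`).
#' @param runs_per_condition independent runs per condition.
#' @param base_seed integer; spawns per-run seeds deterministically.
#' @param topology,coupling_form,duration_s,sample_rate_hz,noise_sigma,...
#'   passed to [sim_config()].
#' @return data.frame with one row per unit (oscillator or mean field) per
#'   run: `group_size`, `coupling`, `condition`, `topology`,
#'   `coupling_form`, `run`, `seed`, `unit`, `freq_hz`, `n_onsets`,
#'   `cov_raw`, `cov_clean`, `valid`, `failed`.
#' @export
run_condition_grid <- function(group_sizes = c(2, 4, 8),
                               coupling = c(0, 8),
                               runs_per_condition = 20,
                               base_seed = 1L,
                               topology = "full",
                               coupling_form = "pulse",
                               duration_s = 100,
                               sample_rate_hz = 300,
                               noise_sigma = 6,
                               ...) {
  stopifnot(length(group_sizes) >= 1, length(coupling) >= 1,
            runs_per_condition >= 1)
  conditions <- expand.grid(N = group_sizes, K = coupling,
                            KEEP.OUT.ATTRS = FALSE)
  set.seed(base_seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1,
                             nrow(conditions) * runs_per_condition),
                  nrow(conditions), runs_per_condition)
  rows <- list()
  for (ci in seq_len(nrow(conditions))) {
    N <- conditions$N[ci]; K <- conditions$K[ci]
    for (run in seq_len(runs_per_condition)) {
      seed <- seeds[ci, run]
      cfg <- sim_config(n_oscillators = N, coupling_strength = K,
                        topology = topology, coupling_form = coupling_form,
                        duration_s = duration_s,
                        sample_rate_hz = sample_rate_hz,
                        noise_sigma = noise_sigma, rng_seed = seed, ...)
      sim <- tryCatch(simulate_pulse_variant(cfg), error = function(e) e)
      if (inherits(sim, "error")) {
        rows[[length(rows) + 1]] <- grid_row(N, K, topology, coupling_form,
                                             run, seed, "run", NA, 0,
                                             NA, NA, FALSE, failed = TRUE)
        next
      }
      for (i in seq_len(N)) {
        tr <- sim$onsets[[i]]
        f_hz <- sim$trajectory$natural_freqs_hz[i]
        st <- cycle_stats(tr, expected_n = duration_s * abs(f_hz))
        rows[[length(rows) + 1]] <- grid_row(N, K, topology, coupling_form,
                                             run, seed, paste0("osc", i),
                                             f_hz, st$n, st$cov_raw,
                                             st$cov_clean, st$valid, FALSE)
      }
      if (N >= 2) {
        mf <- mean_field_onsets(sim$trajectory)
        st <- cycle_stats(mf, expected_n = duration_s * cfg$freq_mean_hz)
        rows[[length(rows) + 1]] <- grid_row(N, K, topology, coupling_form,
                                             run, seed, "mean_field",
                                             NA, st$n, st$cov_raw,
                                             st$cov_clean, st$valid, FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

simulate_pulse_variant <- function(cfg) {
  if (cfg$coupling_form == "pulse") {
    simulate_pulse_coupled(cfg)
  } else {
    traj <- simulate_classic(cfg)
    onsets <- lapply(seq_len(cfg$n_oscillators), function(i) {
      tr <- extract_onsets(traj, i)
      onset_train(unclass(tr), performer_id = paste0("osc", i),
                  source = "oscillator")
    })
    list(trajectory = traj, onsets = onsets)
  }
}

grid_row <- function(N, K, topology, coupling_form, run, seed, unit, freq_hz,
                     n_onsets, cov_raw, cov_clean, valid, failed) {
  data.frame(group_size = N, coupling = K,
             condition = if (K == 0) "solo" else "ensemble",
             topology = topology, coupling_form = coupling_form,
             run = run, seed = seed, unit = unit, freq_hz = freq_hz,
             n_onsets = n_onsets, cov_raw = cov_raw, cov_clean = cov_clean,
             valid = valid, failed = failed,
             stringsAsFactors = FALSE)
}

## raw and cleaned CoV of a train's cycle durations, plus count validity
cycle_stats <- function(train, expected_n) {
  tt <- as.numeric(train)
  n <- length(tt)
  valid <- is.finite(expected_n) && expected_n > 0 &&
    abs(n - expected_n) / expected_n <= 0.5
  if (n < 4) {
    return(list(n = n, cov_raw = NA_real_, cov_clean = NA_real_,
                valid = FALSE))
  }
  d <- diff(tt)
  med <- stats::median(d)
  dc <- d[abs(d - med) / med <= 0.5]
  list(n = n,
       cov_raw = stats::sd(d) / mean(d),
       cov_clean = if (length(dc) >= 3) stats::sd(dc) / mean(dc) else NA_real_,
       valid = valid)
}

#' Summarize a condition grid into the variability pattern
#'
#' Averages cleaned cycle-duration CoV over valid units per condition,
#' separately for individual oscillators and the mean field, and reports
#' the individual-minus-mean-field gap per ensemble group size.
#'
#' @param grid output of [run_condition_grid()].
#' @return list with `by_condition` (data.frame: group_size, condition,
#'   unit_type, mean_cov, n_units, n_excluded) and `gap` (data.frame:
#'   group_size, cov_gap for ensemble runs).
#' @export
summarize_condition_grid <- function(grid) {
  ok <- grid[!grid$failed & !is.na(grid$cov_clean), ]
  ok$unit_type <- ifelse(ok$unit == "mean_field", "mean_field", "individual")
  keep <- ok[ok$valid, ]
  agg <- stats::aggregate(cov_clean ~ group_size + condition + unit_type,
                          keep, mean)
  names(agg)[names(agg) == "cov_clean"] <- "mean_cov"
  cnt <- stats::aggregate(cov_clean ~ group_size + condition + unit_type,
                          keep, length)
  agg$n_units <- cnt$cov_clean
  excl <- stats::aggregate(valid ~ group_size + condition + unit_type, ok,
                           function(v) sum(!v))
  agg <- merge(agg, stats::setNames(excl, c("group_size", "condition",
                                            "unit_type", "n_excluded")),
               all.x = TRUE)
  ens <- agg[agg$condition == "ensemble", ]
  gap <- merge(ens[ens$unit_type == "individual", c("group_size", "mean_cov")],
               ens[ens$unit_type == "mean_field", c("group_size", "mean_cov")],
               by = "group_size", suffixes = c("_individual", "_mean_field"))
  gap$cov_gap <- gap$mean_cov_individual - gap$mean_cov_mean_field
  list(by_condition = agg, gap = gap)
}
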