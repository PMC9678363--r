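#' Run the full model study
#'
#' Reproduces the model side of the study: the pulse-coupled simulator over
#' the crossing of group size and coupling (solo vs ensemble), the
#' pseudo-ensemble baseline (mean field of uncoupled runs), and the two
#' comparison variants (pulse coupling on a ring topology; continuous
#' constant coupling on the full topology). Produces tidy summary tables
#' and a variability-pattern figure.
#'
#' @param group_sizes,coupling,runs_per_condition,duration_s,sample_rate_hz,base_seed
#'   grid parameters, see [run_condition_grid()].
#' @param variants character subset of `c("ring", "continuous")` comparison
#'   models to run alongside the mean-field pulse model.
#' @param out_dir optional directory; when given, tables are written as CSV
#'   and the figure as PDF.
#' @return list with `grid` (full per-unit table), `summary`
#'   (per-condition means), `gap`, `variant_grids`, `variant_summaries`
#'   and `figure` (a ggplot object in the style of the variability figure:
#'   mean CoV by group size, condition and unit type).
#' @export
run_model_study <- function(group_sizes = c(2, 4, 8), coupling = c(0, 8),
                            runs_per_condition = 20, duration_s = 100,
                            sample_rate_hz = 300, base_seed = 1L,
                            variants = c("ring", "continuous"),
                            out_dir = NULL) {
  grid <- run_condition_grid(group_sizes, coupling, runs_per_condition,
                             base_seed, topology = "full",
                             coupling_form = "pulse",
                             duration_s = duration_s,
                             sample_rate_hz = sample_rate_hz)
  summ <- summarize_condition_grid(grid)
  variant_grids <- list()
  if ("ring" %in% variants) {
    ring_n <- group_sizes[group_sizes >= 3]
    if (length(ring_n)) {
      variant_grids$ring <- run_condition_grid(
        ring_n, coupling, runs_per_condition, base_seed + 1L,
        topology = "ring", coupling_form = "pulse",
        duration_s = duration_s, sample_rate_hz = sample_rate_hz)
    }
  }
  if ("continuous" %in% variants) {
    variant_grids$continuous <- run_condition_grid(
      group_sizes, coupling, runs_per_condition, base_seed + 2L,
      topology = "full", coupling_form = "continuous_difference",
      duration_s = duration_s, sample_rate_hz = sample_rate_hz)
  }
  variant_summaries <- lapply(variant_grids, summarize_condition_grid)

  fig <- variability_figure(summ$by_condition)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(grid, file.path(out_dir, "model_grid.csv"),
                     row.names = FALSE)
    utils::write.csv(summ$by_condition,
                     file.path(out_dir, "model_summary.csv"),
                     row.names = FALSE)
    for (nm in names(variant_grids)) {
      utils::write.csv(variant_grids[[nm]],
                       file.path(out_dir, paste0("variant_", nm, "_grid.csv")),
                       row.names = FALSE)
    }
    ggplot2::ggsave(file.path(out_dir, "variability_pattern.pdf"), fig,
                    width = 6, height = 4)
  }
  list(grid = grid, summary = summ$by_condition, gap = summ$gap,
       variant_grids = variant_grids, variant_summaries = variant_summaries,
       figure = fig)
}

variability_figure <- function(by_condition) {
  d <- by_condition
  d$series <- paste(d$unit_type, d$condition, sep = ", ")
  ggplot2::ggplot(d, ggplot2::aes(x = factor(group_size), y = mean_cov,
                                  group = series, colour = series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "group size N", y = "mean CoV of cycle durations",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Run the behavioral analysis pipeline on a set of trials
#'
#' Applies the complete analysis chain to each trial: continuation-phase
#' extraction, per-performer interval cleaning, tempo trend, detrending,
#' pre-whitening and CoV; group-aggregate (or, for solo trials,
#' pseudo-aggregate) construction and the same metrics on it;
#' autocorrelation profiles and their lag range; and for ensemble trials,
#' aligned cross-correlations, the transfer-entropy graph and its network
#' summaries. Solo trials skip the pair-level and network analyses, since
#' performers could not hear each other.
#'
#' @param trials list of [trial_ensemble] objects (or a single one), or a
#'   character path to an event CSV readable by [read_trial()].
#' @param max_lag_acf,max_lag_ccf correlation lag ranges (beats).
#' @param te_bin_width_s,te_max_delay_bins transfer-entropy parameters.
#' @return list of data.frames: `performer_metrics` (one row per performer
#'   and per aggregate, with CoV, tempo slope, tempo deviation),
#'   `acf_profiles`, `acf_range`, `cross_correlations`, `te_edges`,
#'   `network_metrics`.
#' @export
run_behavioral_pipeline <- function(trials, max_lag_acf = 8, max_lag_ccf = 4,
                                    te_bin_width_s = 0.010,
                                    te_max_delay_bins = 100) {
  if (inherits(trials, "trial_ensemble")) trials <- list(trials)
  if (is.character(trials)) trials <- list(read_trial(trials))
  perf <- acfp <- acfr <- ccs <- edges <- net <- list()
  for (trial in trials) {
    res <- tryCatch(
      analyze_trial(trial, max_lag_acf, max_lag_ccf,
                    te_bin_width_s, te_max_delay_bins),
      error = function(e) {
        warning("trial ", trial$trial_id, " failed: ", conditionMessage(e))
        NULL
      })
    if (is.null(res)) next
    perf[[length(perf) + 1]] <- res$performer_metrics
    acfp[[length(acfp) + 1]] <- res$acf_profiles
    acfr[[length(acfr) + 1]] <- res$acf_range
    if (!is.null(res$cross_correlations)) ccs[[length(ccs) + 1]] <- res$cross_correlations
    if (!is.null(res$te_edges)) edges[[length(edges) + 1]] <- res$te_edges
    if (!is.null(res$network_metrics)) net[[length(net) + 1]] <- res$network_metrics
  }
  bind <- function(x) if (length(x)) do.call(rbind, x) else NULL
  list(performer_metrics = bind(perf),
       acf_profiles = bind(acfp),
       acf_range = bind(acfr),
       cross_correlations = bind(ccs),
       te_edges = bind(edges),
       network_metrics = bind(net))
}

analyze_trial <- function(trial, max_lag_acf, max_lag_ccf,
                          te_bin_width_s, te_max_delay_bins) {
  cont <- split_phases(trial)$continuation
  stim_ioi <- 60 / trial$stimulus_tempo_bpm
  is_solo <- identical(trial$condition, "solo")

  agg <- if (is_solo) pseudo_aggregate(cont, stimulus_ioi_s = stim_ioi)
         else if (trial$group_size >= 2) aggregate_onsets(cont, stimulus_ioi_s = stim_ioi)
         else NULL
  units <- cont
  if (!is.null(agg) && length(agg) >= 3) units <- c(cont, list(agg))

  pm <- lapply(units, function(tr) {
    v <- tryCatch(ioi_variability(tr), error = function(e) NULL)
    if (is.null(v)) return(NULL)
    data.frame(trial_id = trial$trial_id,
               performer_id = attr(tr, "performer_id"),
               source = attr(tr, "source"),
               group_size = trial$group_size,
               condition = trial$condition,
               stimulus_tempo_bpm = trial$stimulus_tempo_bpm,
               n_onsets = length(tr),
               cov = v$cov,
               tempo_slope_bpm_per_beat = v$tempo_slope_bpm_per_beat,
               mean_ioi_s = v$mean_ioi_s,
               tempo_deviation_bpm = 60 / v$mean_ioi_s - trial$stimulus_tempo_bpm,
               ar_order = v$ar_order,
               stringsAsFactors = FALSE)
  })
  pm <- do.call(rbind, pm)

  prof_rows <- range_rows <- list()
  for (tr in units) {
    w <- tryCatch(
      suppressWarnings(prewhiten_iois(detrend_iois(
        remove_outlier_iois(to_iois(tr))))),
      error = function(e) NULL)
    if (is.null(w) || sum(w$valid) <= max_lag_acf + 2) next
    prof <- tryCatch(autocorrelation(w, max_lag_acf), error = function(e) NULL)
    if (is.null(prof)) next
    prof_rows[[length(prof_rows) + 1]] <- data.frame(
      trial_id = trial$trial_id, performer_id = attr(tr, "performer_id"),
      source = attr(tr, "source"), lag = prof$lags,
      coefficient = prof$coefficients, stringsAsFactors = FALSE)
    range_rows[[length(range_rows) + 1]] <- data.frame(
      trial_id = trial$trial_id, performer_id = attr(tr, "performer_id"),
      source = attr(tr, "source"),
      acf_range = acf_range(prof, max_lag_acf), stringsAsFactors = FALSE)
  }

  out <- list(performer_metrics = pm,
              acf_profiles = do.call(rbind, prof_rows),
              acf_range = do.call(rbind, range_rows),
              cross_correlations = NULL, te_edges = NULL,
              network_metrics = NULL)
  if (is_solo || trial$group_size < 2) return(out)

  aligned <- align_iois(cont, agg)
  if (nrow(aligned) > max_lag_ccf + 2) {
    cc <- pairwise_cross_correlations(aligned, max_lag_ccf)
    if (nrow(cc)) {
      cc$trial_id <- trial$trial_id
      out$cross_correlations <- cc[, c("trial_id", "pair", "lag", "coefficient")]
    }
  }
  g <- te_graph(cont, bin_width_s = te_bin_width_s,
                max_delay_bins = te_max_delay_bins)
  n <- length(g$nodes)
  src <- rep(g$nodes, each = n); tgt <- rep(g$nodes, n)
  off <- src != tgt
  out$te_edges <- data.frame(trial_id = trial$trial_id,
                             source = src[off], target = tgt[off],
                             te_bits = as.vector(t(g$weights))[off],
                             best_delay = as.vector(t(g$best_delay))[off],
                             stringsAsFactors = FALSE)
  out$network_metrics <- data.frame(trial_id = trial$trial_id,
                                    group_size = trial$group_size,
                                    causal_density = causal_density(g),
                                    mean_node_strength = mean_node_strength(g),
                                    stringsAsFactors = FALSE)
  out
}
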