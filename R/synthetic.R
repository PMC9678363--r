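#' Specification of a synthetic tapper
#'
#' Parameters of a simple stochastic tapper used to generate behavioral-like
#' onset trains with known ground truth: mean interval, Gaussian timing
#' jitter, linear tempo drift, and rates of skipped and inserted hits.
#'
#' @param base_ioi_s mean inter-onset interval (s), positive.
#' @param jitter_sd_s SD of additive Gaussian timing noise per beat (s).
#' @param drift_bpm_per_beat linear tempo drift (bpm per beat; positive
#'   means speeding up).
#' @param p_miss probability a beat is skipped (internal clock continues).
#' @param p_extra probability an extra off-beat hit is inserted after a beat.
#' @return An object of class `tapper_spec`.
#' @export
tapper_spec <- function(base_ioi_s, jitter_sd_s = 0,
                        drift_bpm_per_beat = 0, p_miss = 0, p_extra = 0) {
  stopifnot(base_ioi_s > 0, jitter_sd_s >= 0,
            p_miss >= 0, p_miss < 1, p_extra >= 0, p_extra < 1)
  structure(list(base_ioi_s = base_ioi_s,
                 jitter_sd_s = jitter_sd_s,
                 drift_bpm_per_beat = drift_bpm_per_beat,
                 p_miss = p_miss,
                 p_extra = p_extra),
            class = "tapper_spec")
}

#' Generate a synthetic trial with known ground truth
#'
#' Simulates one trial of one or more tappers. Each tapper produces beats
#' from an internal clock whose tempo follows
#' `T_n = 60 / base_ioi_s + drift_bpm_per_beat * n`, plus Gaussian jitter on
#' each produced onset. With `coupling > 0`, each tapper applies first-order
#' error correction: at every beat it shifts its internal clock by
#' `coupling` times its asynchrony to the group-mean onset of the previous
#' beat, which produces the alternating long-short interval signature
#' (negative lag-1 autocorrelation, negative lag-0 / positive lag-1
#' cross-correlation) characteristic of mutually synchronizing performers.
#' Beats may be skipped (`p_miss`) or followed by an inserted off-beat hit
#' (`p_extra`); the internal clock is unaffected by either.
#'
#' @param specs list of [tapper_spec], one per performer.
#' @param coupling error-correction gain in `[0, 2)`; 0 for independent
#'   (solo-like) tappers. Gains >= 2 are unstable and rejected.
#' @param duration_s trial length (s).
#' @param trial_id,stimulus_tempo_bpm,condition trial metadata; stimulus
#'   tempo defaults to the first tapper's base tempo.
#' @param rng_seed integer seed.
#' @return A [trial_ensemble] (task `"synchronization_only"`, so the full
#'   trial is analyzed).
#' @export
generate_trial <- function(specs, coupling = 0, duration_s = 60,
                           trial_id = "synth1", stimulus_tempo_bpm = NULL,
                           condition = NULL, rng_seed = 1L) {
  if (inherits(specs, "tapper_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1,
            all(vapply(specs, inherits, TRUE, "tapper_spec")))
  if (coupling < 0 || coupling >= 2) {
    stop("coupling gain must be in [0, 2): gains >= 2 are unstable")
  }
  set.seed(rng_seed)
  np <- length(specs)
  if (is.null(stimulus_tempo_bpm)) stimulus_tempo_bpm <- 60 / specs[[1]]$base_ioi_s
  if (is.null(condition)) condition <- if (np >= 2 && coupling > 0) "ensemble" else "solo"

  n_beats <- max(3, ceiling(duration_s / min(vapply(specs, `[[`, 0, "base_ioi_s"))) + 2)
  clock <- vapply(specs, function(sp) 0, 0)       # internal clock time of beat n
  produced <- vector("list", np)                  # emitted (audible) onsets
  for (p in seq_len(np)) produced[[p]] <- numeric(0)
  prev_emit <- rep(NA_real_, np)                  # last beat's emitted time

  for (n in seq_len(n_beats)) {
    ## error correction toward the group-mean onset of the previous beat
    if (coupling > 0 && np >= 2 && all(!is.na(prev_emit))) {
      grp <- mean(prev_emit)
      clock <- clock - coupling * (prev_emit - grp)
    }
    emit <- numeric(np)
    for (p in seq_len(np)) {
      sp <- specs[[p]]
      tempo_n <- 60 / sp$base_ioi_s + sp$drift_bpm_per_beat * (n - 1)
      ioi_n <- 60 / tempo_n
      ## jitter perturbs the produced interval (clock noise), so the interval
      ## CoV of an uncoupled tapper is exactly jitter_sd_s / base_ioi_s
      clock[p] <- clock[p] + ioi_n +
        if (sp$jitter_sd_s > 0) stats::rnorm(1, 0, sp$jitter_sd_s) else 0
      emit[p] <- clock[p]
    }
    prev_emit <- emit
    for (p in seq_len(np)) {
      sp <- specs[[p]]
      if (emit[p] > duration_s) next
      skipped <- sp$p_miss > 0 && stats::runif(1) < sp$p_miss
      if (!skipped && emit[p] >= 0) produced[[p]] <- c(produced[[p]], emit[p])
      if (sp$p_extra > 0 && stats::runif(1) < sp$p_extra) {
        extra <- emit[p] + 0.5 * sp$base_ioi_s +
          if (sp$jitter_sd_s > 0) stats::rnorm(1, 0, sp$jitter_sd_s) else 0
        if (extra > 0 && extra <= duration_s) {
          produced[[p]] <- c(produced[[p]], extra)
        }
      }
    }
  }
  trains <- lapply(seq_len(np), function(p) {
    tt <- sort(produced[[p]])
    tt <- tt[c(TRUE, diff(tt) > 1e-9)]           # guard exact duplicates
    onset_train(tt, performer_id = paste0("tapper", p), source = "human")
  })
  trial_ensemble(trains, trial_id = trial_id,
                 stimulus_tempo_bpm = stimulus_tempo_bpm,
                 sync_end_s = 0, condition = condition,
                 task = "synchronization_only")
}
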