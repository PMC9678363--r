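#' Onset train: one performer's event times within a trial
#'
#' An `onset_train` holds the ordered drum-hit (or oscillator zero-crossing)
#' onset times of a single performer, oscillator, or aggregate within one
#' trial, in seconds from trial start.
#'
#' @param times numeric vector of onset times in seconds, strictly
#'   increasing, all non-negative. May be empty.
#' @param performer_id character or numeric label for the performer.
#' @param source one of `"human"`, `"oscillator"`, `"mean_field"`,
#'   `"aggregate"`.
#' @return An object of class `onset_train`: a numeric vector of times with
#'   `performer_id` and `source` attributes.
#' @export
#' @examples
#' onset_train(c(0.5, 1.0, 1.5), performer_id = "p1")
onset_train <- function(times, performer_id = "p1", source = "human") {
  source <- match.arg(source, c("human", "oscillator", "mean_field", "aggregate"))
  times <- as.numeric(times)
  if (anyNA(times)) stop("onset times must not contain NA")
  if (length(times) && any(times < 0)) {
    stop("onset times must be >= 0 (first offending index: ",
         which(times < 0)[1], ")")
  }
  if (length(times) >= 2 && any(diff(times) <= 0)) {
    stop("onset times must be strictly increasing (first offending index: ",
         which(diff(times) <= 0)[1] + 1, ")")
  }
  structure(times,
            performer_id = as.character(performer_id),
            source = source,
            class = "onset_train")
}

#' @export
print.onset_train <- function(x, ...) {
  cat(sprintf("<onset_train> performer %s (%s): %d onsets",
              attr(x, "performer_id"), attr(x, "source"), length(x)))
  if (length(x)) cat(sprintf(" over [%.3f, %.3f] s", min(x), max(x)))
  cat("\n")
  invisible(x)
}

#' @export
`[.onset_train` <- function(x, i, ...) {
  onset_train(unclass(x)[i],
              performer_id = attr(x, "performer_id"),
              source = attr(x, "source"))
}

is_onset_train <- function(x) inherits(x, "onset_train")

#' Trial ensemble: the onset trains of one trial plus its metadata
#'
#' Bundles one [onset_train] per performer with the trial's stimulus tempo,
#' the synchronization/continuation boundary and condition labels.
#'
#' @param trains list of [onset_train] objects, one per performer.
#' @param trial_id trial label.
#' @param stimulus_tempo_bpm reference metronome tempo in beats per minute.
#' @param sync_end_s time (s) of the last paced stimulus beat; onsets strictly
#'   after this belong to the continuation phase. Use 0 for trials that are
#'   analyzed full-length.
#' @param condition `"solo"` or `"ensemble"`.
#' @param task `"SCT"` (synchronization-continuation) or
#'   `"synchronization_only"`; for the latter, the full trial is analyzed.
#' @return An object of class `trial_ensemble`.
#' @export
trial_ensemble <- function(trains, trial_id = "trial1",
                           stimulus_tempo_bpm = 120, sync_end_s = 0,
                           condition = c("ensemble", "solo"),
                           task = c("SCT", "synchronization_only")) {
  condition <- match.arg(condition)
  task <- match.arg(task)
  if (!is.list(trains) || !length(trains) || !all(vapply(trains, is_onset_train, TRUE))) {
    stop("`trains` must be a non-empty list of onset_train objects")
  }
  if (!is.numeric(stimulus_tempo_bpm) || stimulus_tempo_bpm <= 0) {
    stop("stimulus_tempo_bpm must be positive")
  }
  if (sync_end_s < 0) stop("sync_end_s must be >= 0")
  ids <- vapply(trains, attr, "", "performer_id")
  if (anyDuplicated(ids)) stop("performer ids must be unique within a trial")
  names(trains) <- ids
  structure(list(trial_id = as.character(trial_id),
                 trains = trains,
                 stimulus_tempo_bpm = stimulus_tempo_bpm,
                 sync_end_s = sync_end_s,
                 group_size = length(trains),
                 condition = condition,
                 task = task),
            class = "trial_ensemble")
}

#' @export
print.trial_ensemble <- function(x, ...) {
  cat(sprintf("<trial_ensemble> %s: N=%d (%s, %s), stimulus %g bpm, sync ends %.2f s\n",
              x$trial_id, x$group_size, x$condition, x$task,
              x$stimulus_tempo_bpm, x$sync_end_s))
  for (tr in x$trains) print(tr)
  invisible(x)
}

#' Split a trial into synchronization and continuation phases
#'
#' Partitions every train at the end of the paced (synchronization) phase.
#' The continuation part keeps onsets strictly after `sync_end_s`. For
#' synchronization-only trials the full train is treated as continuation,
#' since such trials are analyzed over their full length.
#'
#' @param trial a [trial_ensemble].
#' @return list with elements `synchronization` and `continuation`, each a
#'   list of [onset_train] objects in the original performer order.
#' @export
split_phases <- function(trial) {
  stopifnot(inherits(trial, "trial_ensemble"))
  cut <- if (identical(trial$task, "synchronization_only")) -Inf else trial$sync_end_s
  sync <- lapply(trial$trains, function(tr) tr[unclass(tr) <= cut])
  cont <- lapply(trial$trains, function(tr) tr[unclass(tr) > cut])
  list(synchronization = sync, continuation = cont)
}

#' Detect onsets in a sampled waveform by thresholding
#'
#' Finds upward threshold crossings in an amplitude signal and suppresses
#' rebound crossings within a refractory interval of the previous accepted
#' onset, mirroring percussion onset extraction from a piezo/drum signal.
#'
#' @param signal numeric vector of sampled amplitudes.
#' @param sample_rate_hz sampling rate of `signal` (Hz), positive.
#' @param threshold amplitude threshold; crossings from below to at-or-above
#'   threshold are candidate onsets.
#' @param refractory_s minimum separation between accepted onsets (s);
#'   default 0.150, the rebound-rejection window for drum hits.
#' @param performer_id,source passed to [onset_train()].
#' @return An [onset_train] of accepted onset times.
#' @export
detect_onsets_from_waveform <- function(signal, sample_rate_hz, threshold,
                                        refractory_s = 0.150,
                                        performer_id = "p1", source = "human") {
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0) {
    stop("sample_rate_hz must be positive")
  }
  if (refractory_s <= 0) stop("refractory_s must be positive")
  signal <- as.numeric(signal)
  above <- signal >= threshold
  rising <- which(above & !c(FALSE, above[-length(above)]))
  times <- (rising - 1) / sample_rate_hz
  keep <- numeric(0)
  last <- -Inf
  for (t in times) {
    if (t - last >= refractory_s) {
      keep <- c(keep, t)
      last <- t
    }
  }
  onset_train(keep, performer_id = performer_id, source = source)
}
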