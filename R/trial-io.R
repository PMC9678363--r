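#' Read and write trials as CSV event tables
#'
#' Trials are serialized as a CSV event table with columns `trial_id`,
#' `performer_id`, `onset_s`, `source`, plus a JSON metadata sidecar
#' (same path with extension `.json`) holding stimulus tempo, phase
#' boundary, condition and task labels. Onset times are written at
#' microsecond precision, so writing and re-reading a trial whose times lie
#' on the microsecond grid round-trips exactly.
#'
#' @param trial a [trial_ensemble].
#' @param path path of the CSV file to write / read.
#' @return `write_trial` invisibly returns `path`; `read_trial` returns the
#'   reconstructed [trial_ensemble].
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "trial_ensemble"))
  rows <- lapply(trial$trains, function(tr) {
    if (!length(tr)) return(NULL)
    data.frame(trial_id = trial$trial_id,
               performer_id = attr(tr, "performer_id"),
               onset_s = sprintf("%.6f", unclass(tr)),
               source = attr(tr, "source"),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- data.frame(trial_id = character(), performer_id = character(),
                      onset_s = character(), source = character())
  }
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  meta <- list(trial_id = trial$trial_id,
               stimulus_tempo_bpm = trial$stimulus_tempo_bpm,
               sync_end_s = trial$sync_end_s,
               condition = trial$condition,
               task = trial$task,
               performers = lapply(trial$trains, function(tr) {
                 list(performer_id = attr(tr, "performer_id"),
                      source = attr(tr, "source"))
               }))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.csv$", ".json", path, ignore.case = TRUE)

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(onset_s = "character"))
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = FALSE)
  trains <- lapply(meta$performers, function(p) {
    rows <- tab$performer_id == p$performer_id
    times <- as.numeric(tab$onset_s[rows])
    if (length(times)) {
      if (any(times < 0)) {
        stop("negative onset time at row ", which(rows)[which(times < 0)[1]],
             " of ", path)
      }
      if (length(times) >= 2 && any(diff(times) <= 0)) {
        bad <- which(diff(times) <= 0)[1] + 1
        stop("onset times not strictly increasing at row ",
             which(rows)[bad], " of ", path)
      }
    }
    onset_train(times, performer_id = p$performer_id, source = p$source)
  })
  trial_ensemble(trains,
                 trial_id = meta$trial_id,
                 stimulus_tempo_bpm = meta$stimulus_tempo_bpm,
                 sync_end_s = meta$sync_end_s,
                 condition = meta$condition,
                 task = meta$task)
}
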