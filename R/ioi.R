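#' Inter-onset-interval series
#'
#' Successive inter-onset intervals `IOI_n = t_n - t_(n-1)` of one onset
#' train, with beat indices, instantaneous tempo `T_n = 60 / IOI_n` (bpm)
#' and per-interval validity flags. The mean of the raw intervals is carried
#' along the processing pipeline so that the coefficient of variation can be
#' referenced to the raw tempo after detrending and pre-whitening.
#'
#' @param train an [onset_train] with at least two onsets, or a numeric
#'   vector of onset times.
#' @return An object of class `ioi_series`: a list with `beat_index`,
#'   `ioi_s`, `tempo_bpm`, `valid`, `raw_mean_ioi_s` and a `stage` marker
#'   (`"raw"`, `"outliers_removed"`, `"detrended"` or `"prewhitened"`).
#' @export
#' @examples
#' to_iois(onset_train(c(0, 0.5, 1.0)))
to_iois <- function(train) {
  times <- as.numeric(train)
  if (length(times) < 2) stop("need at least 2 onsets to form IOIs")
  ioi <- diff(times)
  new_ioi_series(beat_index = seq_along(ioi),
                 ioi_s = ioi,
                 valid = rep(TRUE, length(ioi)),
                 raw_mean_ioi_s = mean(ioi),
                 stage = "raw",
                 performer_id = if (is_onset_train(train))
                   attr(train, "performer_id") else "p1")
}

new_ioi_series <- function(beat_index, ioi_s, valid, raw_mean_ioi_s, stage,
                           performer_id) {
  structure(list(beat_index = beat_index,
                 ioi_s = ioi_s,
                 tempo_bpm = if (stage %in% c("raw", "outliers_removed"))
                   60 / ioi_s else rep(NA_real_, length(ioi_s)),
                 valid = valid,
                 raw_mean_ioi_s = raw_mean_ioi_s,
                 stage = stage,
                 performer_id = performer_id),
            class = "ioi_series")
}

#' @export
print.ioi_series <- function(x, ...) {
  cat(sprintf("<ioi_series> %s: %d intervals (%d valid), stage '%s', raw mean %.3f s\n",
              x$performer_id, length(x$ioi_s), sum(x$valid), x$stage,
              x$raw_mean_ioi_s))
  invisible(x)
}

ioi_values <- function(x) x$ioi_s[x$valid]

#' Remove outlier intervals relative to the trial median
#'
#' Flags as invalid any interval differing from the trial median by more
#' than `rel_threshold` (default 50%) in either direction — the signature
#' of a skipped beat (a doubled interval) or a spurious extra hit. The
#' median is computed once from all intervals of the series.
#'
#' @param series an `ioi_series`.
#' @param rel_threshold maximum allowed relative deviation from the median.
#' @return The series with outliers flagged invalid, stage
#'   `"outliers_removed"`.
#' @export
remove_outlier_iois <- function(series, rel_threshold = 0.5) {
  stopifnot(inherits(series, "ioi_series"), length(series$ioi_s) > 0)
  med <- stats::median(series$ioi_s)
  ok <- abs(series$ioi_s - med) / med <= rel_threshold
  new_ioi_series(series$beat_index, series$ioi_s,
                 valid = series$valid & ok,
                 raw_mean_ioi_s = series$raw_mean_ioi_s,
                 stage = "outliers_removed",
                 performer_id = series$performer_id)
}

#' Linear tempo trend across beats
#'
#' Ordinary least-squares slope of the instantaneous tempo
#' `T_n = 60 / IOI_n` against beat index `n`, fitted per trial. A positive
#' slope means the performer is speeding up.
#'
#' @param series an `ioi_series` at a stage where tempo is defined
#'   (raw or outliers removed).
#' @return slope in bpm per beat.
#' @export
tempo_trend <- function(series) {
  stopifnot(inherits(series, "ioi_series"))
  n <- series$beat_index[series$valid]
  tempo <- series$tempo_bpm[series$valid]
  if (length(n) < 3) stop("need at least 3 valid intervals for a trend")
  if (anyNA(tempo)) stop("tempo undefined at stage '", series$stage, "'")
  if (stats::var(n) == 0) stop("degenerate beat indices")
  unname(stats::coef(stats::lm(tempo ~ n))[2])
}

#' Remove the linear interval trend
#'
#' Subtracts the OLS linear fit of the interval on beat index, leaving
#' residual intervals; the raw-interval mean is preserved for later use as
#' the coefficient-of-variation denominator.
#'
#' @param series an `ioi_series`.
#' @return The detrended series (stage `"detrended"`).
#' @export
detrend_iois <- function(series) {
  stopifnot(inherits(series, "ioi_series"))
  n <- series$beat_index[series$valid]
  y <- series$ioi_s[series$valid]
  if (length(n) < 3) stop("need at least 3 valid intervals to detrend")
  if (stats::var(n) == 0) stop("degenerate beat indices")
  res <- stats::residuals(stats::lm(y ~ n))
  out <- series$ioi_s
  out[series$valid] <- res
  new_ioi_series(series$beat_index, out, series$valid,
                 raw_mean_ioi_s = series$raw_mean_ioi_s,
                 stage = "detrended",
                 performer_id = series$performer_id)
}

#' Pre-whiten an interval series with an autoregressive filter
#'
#' Fits an AR model to the valid intervals with automatic order selection
#' (AIC, orders 0..`max_order`) and returns the innovation series, removing
#' serial dependence before correlation analysis. Each series is filtered
#' with its own model.
#'
#' @param series an `ioi_series` (conventionally already detrended).
#' @param max_order maximum AR order considered; default
#'   `min(10, floor(n / 5))`.
#' @return The whitened series (stage `"prewhitened"`). Series with fewer
#'   than 10 valid intervals are returned unchanged with a warning;
#'   zero-variance series return centered zeros with a warning.
#' @export
prewhiten_iois <- function(series, max_order = NULL) {
  stopifnot(inherits(series, "ioi_series"))
  y <- series$ioi_s[series$valid]
  n <- length(y)
  if (n < 10) {
    warning("fewer than 10 valid intervals; returning series unchanged")
    return(series)
  }
  if (is.null(max_order)) max_order <- min(10, floor(n / 5))
  if (stats::var(y) == 0) {
    warning("zero-variance series; returning centered zeros")
    out <- series$ioi_s
    out[series$valid] <- 0
    return(new_ioi_series(series$beat_index, out, series$valid,
                          series$raw_mean_ioi_s, "prewhitened",
                          series$performer_id))
  }
  fit <- tryCatch(
    stats::ar(y, aic = TRUE, order.max = max_order, method = "yule-walker"),
    error = function(e) NULL)
  if (is.null(fit) || any(!is.finite(fit$ar)) ||
      (fit$order > 0 && any(Mod(polyroot(c(1, -fit$ar))) <= 1))) {
    warning("unstable AR fit; falling back to order 0")
    innov <- y - mean(y)
    ord <- 0L
  } else {
    ord <- fit$order
    innov <- as.numeric(fit$resid)
    innov[seq_len(ord)] <- 0   # first p innovations are undefined
  }
  out <- series$ioi_s
  out[series$valid] <- innov
  res <- new_ioi_series(series$beat_index, out, series$valid,
                        series$raw_mean_ioi_s, "prewhitened",
                        series$performer_id)
  res$ar_order <- ord
  res
}

#' Coefficient of variation of processed intervals
#'
#' SD of the (conventionally detrended and pre-whitened) interval values
#' divided by the mean of the raw intervals. The raw mean is used as the
#' denominator because the processed residuals are centered near zero.
#'
#' @param series an `ioi_series`.
#' @return dimensionless CoV.
#' @export
coefficient_of_variation <- function(series) {
  stopifnot(inherits(series, "ioi_series"))
  if (!is.finite(series$raw_mean_ioi_s) || series$raw_mean_ioi_s == 0) {
    stop("raw mean interval is zero; CoV undefined")
  }
  stats::sd(ioi_values(series)) / series$raw_mean_ioi_s
}

#' Full per-train variability pipeline
#'
#' Convenience wrapper enforcing the processing order: outlier removal,
#' linear detrend, AR pre-whitening, then the coefficient of variation.
#'
#' @param train an [onset_train].
#' @param rel_threshold outlier threshold, see [remove_outlier_iois()].
#' @return list with `cov`, `tempo_slope_bpm_per_beat`, `n_valid`,
#'   `ar_order`, `mean_ioi_s`.
#' @export
ioi_variability <- function(train, rel_threshold = 0.5) {
  s <- remove_outlier_iois(to_iois(train), rel_threshold)
  slope <- tryCatch(tempo_trend(s), error = function(e) NA_real_)
  w <- suppressWarnings(prewhiten_iois(detrend_iois(s)))
  list(cov = coefficient_of_variation(w),
       tempo_slope_bpm_per_beat = slope,
       n_valid = sum(w$valid),
       ar_order = if (is.null(w$ar_order)) NA_integer_ else w$ar_order,
       mean_ioi_s = w$raw_mean_ioi_s)
}

#' Align intervals across performers via aggregate beat slots
#'
#' Matches each performer's onsets to the aggregate train's beat slots by
#' temporal adjacency (nearest neighbor within half the aggregate's median
#' interval), then keeps only the beat-to-beat intervals for which every
#' performer has exactly one matched onset at both endpoints. When one
#' performer skips a beat, the two intervals flanking that beat are dropped
#' for all performers.
#'
#' @param trains list of >= 2 [onset_train] objects.
#' @param aggregate_train an [onset_train] of aggregate beats defining the
#'   slots (see [aggregate_onsets()]); if `NULL`, computed from `trains`
#'   with `stimulus_ioi_s` taken as the median pooled interval.
#' @return A numeric matrix (class `aligned_ioi_matrix`) with one row per
#'   retained beat slot and one column per performer; attribute
#'   `slot_index` gives the aggregate slot of each row's right endpoint.
#'   Zero-row matrix (with a warning) if no slot is shared.
#' @export
align_iois <- function(trains, aggregate_train = NULL) {
  stopifnot(is.list(trains), length(trains) >= 2)
  if (is.null(aggregate_train)) {
    pooled <- sort(unlist(lapply(trains, as.numeric)))
    agg_ioi <- stats::median(diff(pooled)) * length(trains)
    aggregate_train <- aggregate_onsets(trains, stimulus_ioi_s = agg_ioi)
  }
  slots <- as.numeric(aggregate_train)
  n_slots <- length(slots)
  if (n_slots < 2) {
    warning("fewer than two aggregate slots; empty alignment")
    return(empty_alignment(trains))
  }
  win <- stats::median(diff(slots)) / 2
  ## matched[s, p] = onset time of performer p assigned to slot s, NA if none
  matched <- matrix(NA_real_, n_slots, length(trains))
  for (p in seq_along(trains)) {
    tt <- as.numeric(trains[[p]])
    if (!length(tt)) next
    ## nearest slot for each onset, then require uniqueness within window
    slot_of <- vapply(tt, function(t) which.min(abs(slots - t)), 0L)
    off <- abs(tt - slots[slot_of])
    for (s in unique(slot_of)) {
      cand <- which(slot_of == s & off <= win)
      if (length(cand) == 1) matched[s, p] <- tt[cand]
      ## 0 or >1 candidate onsets: slot unmatched for this performer
    }
  }
  complete <- !apply(is.na(matched), 1, any)
  rows <- which(complete[-1] & complete[-n_slots]) + 1L  # both endpoints matched
  if (!length(rows)) {
    warning("no beat slot matched by all performers; empty alignment")
    return(empty_alignment(trains))
  }
  m <- matched[rows, , drop = FALSE] - matched[rows - 1L, , drop = FALSE]
  colnames(m) <- vapply(trains, attr, "", "performer_id")
  structure(m, slot_index = rows, class = c("aligned_ioi_matrix", class(m)))
}

empty_alignment <- function(trains) {
  m <- matrix(numeric(0), 0, length(trains))
  colnames(m) <- vapply(trains, attr, "", "performer_id")
  structure(m, slot_index = integer(0),
            class = c("aligned_ioi_matrix", class(m)))
}
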