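#' Autocorrelation profile of an interval series
#'
#' Sample autocorrelation of the (conventionally cleaned and pre-whitened)
#' intervals at lags 0..`max_lag`, with the biased (1/n) covariance
#' normalization so that the lag-0 coefficient is exactly 1.
#'
#' @param series an `ioi_series` or numeric vector.
#' @param max_lag maximum lag in beats (default 8).
#' @return An object of class `correlation_profile`: list with `lags`
#'   (0..max_lag) and `coefficients`.
#' @export
autocorrelation <- function(series, max_lag = 8) {
  y <- if (inherits(series, "ioi_series")) ioi_values(series) else as.numeric(series)
  n <- length(y)
  if (n <= max_lag + 2) stop("series too short for max_lag = ", max_lag)
  if (stats::var(y) == 0) stop("zero-variance series has no autocorrelation")
  co <- as.numeric(stats::acf(y, lag.max = max_lag, plot = FALSE,
                              demean = TRUE, type = "correlation")$acf)
  stopifnot(all(abs(co) <= 1 + 1e-12))
  structure(list(lags = 0:max_lag, coefficients = pmin(1, pmax(-1, co))),
            class = "correlation_profile")
}

#' @export
print.correlation_profile <- function(x, ...) {
  cat("<correlation_profile> lags", min(x$lags), "..", max(x$lags), "\n")
  print(round(stats::setNames(x$coefficients, x$lags), 3))
  invisible(x)
}

#' Average range of the autocorrelation function
#'
#' The mean absolute difference between coefficients at successive lags up
#' to `up_to_lag`, a scalar summary of how strongly the autocorrelation
#' function oscillates: alternating long-short interval dynamics score high,
#' smooth profiles score low.
#'
#' @param profile a `correlation_profile` covering lags 0..`up_to_lag`.
#' @param up_to_lag last lag included (default 8).
#' @return mean of `|rho(k) - rho(k-1)|` for k = 1..`up_to_lag`.
#' @export
acf_range <- function(profile, up_to_lag = 8) {
  stopifnot(inherits(profile, "correlation_profile"))
  if (max(profile$lags) < up_to_lag) {
    stop("profile does not reach lag ", up_to_lag)
  }
  co <- profile$coefficients[match(0:up_to_lag, profile$lags)]
  mean(abs(diff(co)))
}

#' Cross-correlation profile between two aligned interval series
#'
#' Pearson cross-correlation with the biased normalization at lags
#' `-max_lag .. +max_lag`. The lag convention: the coefficient at positive
#' lag k is `cor(x_t, y_(t-k))`, i.e. positive lags mean `x` follows `y`
#' by k beats.
#'
#' @param x,y `ioi_series` or numeric vectors of equal length (same beat
#'   slots, conventionally pre-whitened).
#' @param max_lag maximum lag in beats (default 4).
#' @return A `correlation_profile` with lags `-max_lag..max_lag`.
#' @export
cross_correlation <- function(x, y, max_lag = 4) {
  xv <- if (inherits(x, "ioi_series")) ioi_values(x) else as.numeric(x)
  yv <- if (inherits(y, "ioi_series")) ioi_values(y) else as.numeric(y)
  if (length(xv) != length(yv)) stop("series lengths differ")
  n <- length(xv)
  if (n <= max_lag + 2) stop("series too short for max_lag = ", max_lag)
  ## ccf lag k: cor(x_{t+k}, y_t) = cor(x_t, y_{t-k})
  co <- as.numeric(stats::ccf(xv, yv, lag.max = max_lag, plot = FALSE,
                              demean = TRUE, type = "correlation")$acf)
  stopifnot(all(abs(co) <= 1 + 1e-12))
  structure(list(lags = -max_lag:max_lag, coefficients = pmin(1, pmax(-1, co))),
            class = "correlation_profile")
}

#' Per-pair cross-correlation profiles within a trial
#'
#' Computes [cross_correlation()] for every unordered performer pair of an
#' aligned interval matrix, after pre-whitening each column, and returns a
#' tidy table; trial-level summaries average the coefficients per lag.
#'
#' @param aligned an `aligned_ioi_matrix` (see [align_iois()]).
#' @param max_lag maximum lag in beats.
#' @param prewhiten whether to AR-prewhiten each performer's column first
#'   (default TRUE).
#' @return data.frame with columns `pair`, `lag`, `coefficient`.
#' @export
pairwise_cross_correlations <- function(aligned, max_lag = 4,
                                        prewhiten = TRUE) {
  stopifnot(inherits(aligned, "aligned_ioi_matrix"))
  p <- ncol(aligned)
  if (p < 2 || nrow(aligned) <= max_lag + 2) {
    return(data.frame(pair = character(), lag = integer(),
                      coefficient = numeric()))
  }
  cols <- lapply(seq_len(p), function(j) {
    y <- aligned[, j]
    if (!prewhiten) return(y)
    s <- new_ioi_series(seq_along(y), y, rep(TRUE, length(y)),
                        mean(y), "detrended", colnames(aligned)[j])
    ioi_values(suppressWarnings(prewhiten_iois(s)))
  })
  out <- list()
  for (a in seq_len(p - 1)) {
    for (b in (a + 1):p) {
      prof <- cross_correlation(cols[[a]], cols[[b]], max_lag)
      out[[length(out) + 1]] <- data.frame(
        pair = paste(colnames(aligned)[a], colnames(aligned)[b], sep = "-"),
        lag = prof$lags,
        coefficient = prof$coefficients)
    }
  }
  do.call(rbind, out)
}
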