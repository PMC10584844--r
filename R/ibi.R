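#' Resample an R-peak series to a regular IBI series
#'
#' The interbeat interval is treated as a step function of time: the sample
#' at time \code{t} takes the value (ms) of the interval containing
#' \code{t}, with the right-closed convention that interval
#' \code{(t[i], t[i+1]]} covers the samples in that span. Samples at or
#' before the first peak and after the last peak are invalid. The grid is
#' \code{t = j / rate}, \code{j = 1, 2, ...}, anchored at recording start so
#' both partners share the same sample times.
#'
#' @param rpeaks an [rpeaks()] series.
#' @param rate sampling rate, Hz.
#' @return list with \code{values} (ms), \code{valid} (logical),
#'   \code{times_s} and \code{rate}.
#' @export
resample_ibi <- function(rpeaks, rate = 10) {
  stopifnot(inherits(rpeaks, "rpeaks"))
  tt <- rpeaks$times_s
  n_samp <- floor(rpeaks$duration_s * rate + 1e-9)
  grid <- seq_len(n_samp) / rate
  # index i with t[i] < grid <= t[i+1]
  idx <- findInterval(grid, tt, left.open = TRUE)
  valid <- idx >= 1L & idx < length(tt)
  ibi <- diff(tt) * 1000
  values <- rep(NA_real_, n_samp)
  values[valid] <- ibi[idx[valid]]
  list(values = values, valid = valid, times_s = grid, rate = rate)
}

#' Average a resampled IBI series into per-second epoch means
#'
#' Epoch \code{j} (half-open \code{[j, j+1)} seconds from recording start,
#' 0-based) is the mean of its \code{rate * epoch_s} samples at times
#' \code{j + 1/rate, ..., j + 1}. An epoch containing any invalid sample is
#' invalid rather than partially averaged.
#'
#' @param series10 output of [resample_ibi()].
#' @param epoch_s epoch length, seconds; \code{rate * epoch_s} must be a
#'   whole number.
#' @return an \code{epoch_series}: list with \code{values} (ms, NA where
#'   invalid), \code{valid}, \code{epoch_s}, \code{start_s}, \code{n_epochs}.
#' @export
epoch_means <- function(series10, epoch_s = 1) {
  per <- series10$rate * epoch_s
  if (abs(per - round(per)) > 1e-9) stop("rate * epoch_s must be integral")
  per <- as.integer(round(per))
  n_epochs <- length(series10$values) %/% per
  use <- seq_len(n_epochs * per)
  g <- rep(seq_len(n_epochs), each = per)
  vals <- as.numeric(tapply(series10$values[use], g, mean))
  ok <- as.logical(tapply(series10$valid[use], g, all))
  vals[!ok] <- NA_real_
  structure(list(values = vals, valid = ok, epoch_s = epoch_s,
                 start_s = 0, n_epochs = n_epochs),
            class = "epoch_series")
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf("IBI epoch-means series: %d epochs of %g s, %d valid (mean %.1f ms)\n",
              x$n_epochs, x$epoch_s, sum(x$valid),
              mean(x$values[x$valid])))
  invisible(x)
}

#' Per-second IBI epoch means from R-peaks
#'
#' Convenience composition of [resample_ibi()] and [epoch_means()] with the
#' configured rates.
#'
#' @param rpeaks an [rpeaks()] series.
#' @param config a [pipeline_config()].
#' @return an \code{epoch_series}.
#' @export
ibi_epoch_series <- function(rpeaks, config = pipeline_config()) {
  epoch_means(resample_ibi(rpeaks, config$resample_hz), config$epoch_s)
}
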