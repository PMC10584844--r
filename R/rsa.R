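#' Discrete prolate spheroidal (Slepian) taper bank
#'
#' Computes the first \code{k} Slepian sequences of length \code{n} at
#' time-bandwidth product \code{nw} by the classical symmetric tridiagonal
#' eigenproblem, orthonormalised to unit energy. These are the tapers of the
#' multitaper band-power estimator; their spectral concentration band is
#' \code{nw / n} cycles per sample on either side of a line.
#'
#' @param n taper length, samples.
#' @param nw time-bandwidth product.
#' @param k number of tapers (concentration degrades beyond \code{2 nw - 2}).
#' @return an \code{n} x \code{k} matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw = 2.5, k = 3) {
  stopifnot(n >= 2, nw > 0, k >= 1, k <= n)
  w <- nw / n
  t <- 0:(n - 1)
  d <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  e <- (t[-1] * (n - t[-1])) / 2
  A <- diag(d)
  for (i in seq_len(n - 1)) {
    A[i, i + 1] <- e[i]
    A[i + 1, i] <- e[i]
  }
  ev <- eigen(A, symmetric = TRUE)
  V <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    v <- V[, j] / sqrt(sum(V[, j]^2))
    if (sum(v) < 0) v <- -v           # sign convention only
    V[, j] <- v
  }
  V
}

#' Spline-interpolate an R-peak series to a uniform IBI series
#'
#' A natural cubic spline is fit through the points
#' \code{(t[i+1], IBI[i])} -- each interval plotted at the beat that closes
#' it -- and evaluated on the fixed grid \code{t = j / rate},
#' \code{j = 0, 1, ...}, making the IBI series equidistant. Samples outside
#' the peak range are invalid.
#'
#' @param rpeaks an [rpeaks()] series with at least 4 peaks.
#' @param rate interpolation rate, Hz.
#' @return list with \code{values} (ms), \code{valid}, \code{times_s},
#'   \code{rate}.
#' @export
interpolate_ibi <- function(rpeaks, rate = 4) {
  stopifnot(inherits(rpeaks, "rpeaks"))
  tt <- rpeaks$times_s
  if (length(tt) < 4L) stop("insufficient data: need at least 4 R-peaks for the spline")
  knots_x <- tt[-1]
  knots_y <- diff(tt) * 1000
  grid <- (0:floor(rpeaks$duration_s * rate + 1e-9)) / rate
  y <- stats::spline(knots_x, knots_y, xout = grid, method = "natural")$y
  valid <- grid >= tt[1] - 1e-9 & grid <= tt[length(tt)] + 1e-9
  y[!valid] <- NA_real_
  list(values = y, valid = valid, times_s = grid, rate = rate)
}

#' Sliding multitaper band power at 1-s resolution
#'
#' A short-time multitaper estimate over sliding windows hopping by
#' \code{window_s - overlap_s} seconds (1 s with defaults). Each 128-sample
#' segment is demeaned, multiplied by each taper, Fourier transformed, the
#' squared magnitudes accumulated across tapers with equal weights, and the
#' bins whose frequency lies in \code{band} summed. The estimate is assigned
#' to the window's centre second; the first and final
#' \code{floor((window_s - 1) / 2)} seconds of the recording carry no
#' estimate. At the two edges of the valid sample span the window is clamped
#' inward by up to \code{max_shift_s} so the boundary seconds closest to the
#' margin still receive an estimate from the nearest full window.
#'
#' @param x4 uniform IBI series from [interpolate_ibi()].
#' @param window_s window length, seconds.
#' @param overlap_s overlap between successive windows, seconds.
#' @param band length-2 numeric frequency band (low, high), Hz.
#' @param taper_bank matrix of orthonormal tapers (rows = window samples);
#'   defaults to [dpss_tapers()] of the right length.
#' @param nw,k taper-bank parameters used when \code{taper_bank} is NULL.
#' @param max_shift_s maximum inward clamp of an edge window, seconds.
#' @return list with \code{power} (per second, NA where no estimate),
#'   \code{valid}, \code{center_s} (0-based second indices).
#' @export
sliding_band_power <- function(x4, window_s = 32, overlap_s = 31,
                               band = c(0.12, 0.40), taper_bank = NULL,
                               nw = 2.5, k = 3, max_shift_s = 2) {
  rate <- x4$rate
  nwin <- as.integer(round(window_s * rate))
  hop <- window_s - overlap_s
  if (hop <= 0) stop("overlap must be < window")
  if (is.null(taper_bank)) taper_bank <- dpss_tapers(nwin, nw, k)
  stopifnot(nrow(taper_bank) == nwin)
  freqs <- (0:(nwin - 1)) * rate / nwin
  in_band <- freqs >= band[1] & freqs <= band[2] & freqs <= rate / 2
  vi <- which(x4$valid)
  n_sec <- floor(length(x4$values) / rate)
  margin <- floor((window_s - 1) / 2)
  centers <- seq.int(margin, n_sec - margin - 1, by = hop)
  centers <- centers[centers >= margin]
  power <- rep(NA_real_, n_sec)
  if (length(vi) < nwin) {
    return(list(power = power, valid = rep(FALSE, n_sec), center_s = 0:(n_sec - 1)))
  }
  jmin <- vi[1]                       # 1-based index of first valid sample
  jmax <- vi[length(vi)]
  max_shift <- as.integer(round(max_shift_s * rate))
  for (c0 in centers) {
    i0 <- as.integer(round(rate * (c0 + 0.5) - nwin / 2)) + 1L  # 1-based
    shift <- 0L
    if (i0 < jmin) { shift <- jmin - i0; i0 <- jmin }
    if (i0 + nwin - 1L > jmax) { shift <- i0 + nwin - 1L - jmax; i0 <- jmax - nwin + 1L }
    if (i0 < jmin || shift > max_shift) next
    seg <- x4$values[i0:(i0 + nwin - 1L)]
    if (anyNA(seg)) next
    seg <- seg - mean(seg)
    acc <- 0
    for (jt in seq_len(ncol(taper_bank))) {
      acc <- acc + Mod(stats::fft(seg * taper_bank[, jt]))^2
    }
    power[c0 + 1L] <- sum(acc[in_band]) / ncol(taper_bank)
  }
  list(power = power, valid = !is.na(power), center_s = 0:(n_sec - 1))
}

#' Natural-log transform band powers into an RSA series
#'
#' @param bp output of [sliding_band_power()].
#' @param band,window_s,overlap_s metadata echoed into the result.
#' @param eps additive guard before the log (ms^2), far below any
#'   physiological band power; keeps degenerate inputs finite.
#' @return an object of class \code{rsa_series}: list with \code{values}
#'   (ln ms^2 per second, NA where invalid), \code{valid}, and the spectral
#'   parameters.
#' @export
rsa_series <- function(bp, band = c(0.12, 0.40), window_s = 32,
                       overlap_s = 31, eps = 1e-12) {
  if (any(bp$power < 0, na.rm = TRUE)) stop("band powers must be nonnegative")
  vals <- log(bp$power + eps)
  vals[!bp$valid] <- NA_real_
  structure(list(values = vals, valid = bp$valid, band_hz = band,
                 window_s = window_s, overlap_s = overlap_s, eps = eps),
            class = "rsa_series")
}

#' @export
print.rsa_series <- function(x, ...) {
  cat(sprintf("RSA series: %d s, %d valid; band %.2f-%.2f Hz, %g-s windows / %g-s overlap\n",
              length(x$values), sum(x$valid), x$band_hz[1], x$band_hz[2],
              x$window_s, x$overlap_s))
  invisible(x)
}

#' Second-by-second RSA from R-peaks
#'
#' Composition of [interpolate_ibi()], [sliding_band_power()] and
#' [rsa_series()] with the configured parameters: the second-by-second
#' natural-log respiration-band power of the interbeat-interval series.
#'
#' @param rpeaks an [rpeaks()] series.
#' @param config a [pipeline_config()].
#' @return an \code{rsa_series}.
#' @export
rsa_epoch_series <- function(rpeaks, config = pipeline_config()) {
  x4 <- interpolate_ibi(rpeaks, config$rsa_interp_hz)
  bp <- sliding_band_power(x4, config$rsa_window_s, config$rsa_overlap_s,
                           config$rsa_band_hz, nw = config$rsa_nw,
                           k = config$rsa_k)
  rsa_series(bp, config$rsa_band_hz, config$rsa_window_s, config$rsa_overlap_s)
}
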