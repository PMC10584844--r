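#' Remove a polynomial trend by least squares
#'
#' Fits \code{values ~ 1 + t + ... + t^order} over the valid samples and
#' returns the fit residuals; removes slow drift (linear and quadratic with
#' the default order 2) before ARIMA pre-whitening.
#'
#' @param values numeric per-second series (NAs allowed, dropped from the
#'   fit and from the output).
#' @param order polynomial order.
#' @return list with \code{residuals} (at the valid samples), \code{coef}
#'   (raw-basis polynomial coefficients) and \code{index} (positions of the
#'   valid samples in the input).
#' @export
detrend_poly <- function(values, order = 2) {
  idx <- which(!is.na(values))
  if (length(idx) <= order + 1) stop("series too short for the polynomial order")
  t <- idx - 1
  if (length(unique(t)) <= order) stop("degenerate design for polynomial detrend")
  X <- outer(t, 0:order, `^`)
  fit <- stats::lm.fit(X, values[idx])
  list(residuals = fit$residuals, coef = fit$coefficients, index = idx)
}

#' Pre-whiten a detrended series with an ARIMA model
#'
#' Fits an ARIMA model (default order (1,1,1): one autoregressive term, one
#' moving-average term and integrated noise) without a constant by maximum
#' likelihood and returns the one-step-ahead innovation residuals. One
#' sample is lost to differencing. If the maximum-likelihood fit fails to
#' converge, an AR(1) on the first differences is used instead and flagged;
#' a series that is constant after differencing yields all-zero residuals
#' with a degenerate flag.
#'
#' @param residuals detrended per-second values.
#' @param order length-3 integer (p, d, q).
#' @return an object of class \code{residual_series}: list with
#'   \code{values} (innovations, length n - d), and a \code{report} carrying
#'   the AR/MA estimates, the model used and a convergence flag.
#' @export
arima_prewhiten <- function(residuals, order = c(1, 1, 1)) {
  x <- as.numeric(residuals)
  n <- length(x)
  if (n < 30) stop("series too short for stable ARIMA estimation (need >= 30)")
  d <- order[2]
  dx <- if (d > 0) diff(x, differences = d) else x
  if (stats::var(dx) < 1e-24) {
    return(structure(list(values = numeric(n - d),
                          report = list(model = "degenerate", ar = NA_real_,
                                        ma = NA_real_, converged = FALSE,
                                        degenerate = TRUE)),
                     class = "residual_series"))
  }
  fit <- tryCatch(
    suppressWarnings(stats::arima(x, order = order, include.mean = FALSE,
                                  method = "ML")),
    error = function(e) NULL)
  if (is.null(fit)) {
    fit <- tryCatch(
      suppressWarnings(stats::arima(x, order = order, include.mean = FALSE,
                                    method = "CSS-ML")),
      error = function(e) NULL)
  }
  if (!is.null(fit)) {
    co <- stats::coef(fit)
    rep_ <- list(model = paste0("arima(", paste(order, collapse = ","), ")"),
                 ar = unname(co["ar1"]), ma = unname(co["ma1"]),
                 converged = fit$code == 0, degenerate = FALSE)
    res <- as.numeric(stats::residuals(fit))
    if (d > 0) res <- res[-seq_len(d)]
    return(structure(list(values = res, report = rep_),
                     class = "residual_series"))
  }
  # fallback: AR(1) on first differences
  warning("ARIMA fit failed to converge; falling back to AR(1) on differences")
  fb <- stats::arima(dx, order = c(1, 0, 0), include.mean = FALSE)
  structure(list(values = as.numeric(stats::residuals(fb)),
                 report = list(model = "ar1-diff-fallback",
                               ar = unname(stats::coef(fb)["ar1"]),
                               ma = NA_real_, converged = FALSE,
                               degenerate = FALSE)),
            class = "residual_series")
}

# detrend + ARIMA pre-whitening of one per-second series (epoch means or RSA).
prewhiten_series <- function(values, config = pipeline_config()) {
  dt <- detrend_poly(values, config$detrend_order)
  pw <- arima_prewhiten(dt$residuals, config$arima_order)
  pw$report$detrend_coef <- dt$coef
  pw
}

#' Lagged cross-correlation profile of two residual series
#'
#' \code{r(k)} is the Pearson correlation of \code{mother[t]} with
#' \code{child[t + k]} over the overlapping index range, computed with
#' per-lag re-centering on each lag's own overlap, for integer lags
#' \code{-max_lag .. +max_lag} seconds. Positive \code{k} therefore
#' quantifies mother-precedes-child covariation and negative \code{k}
#' child-precedes-mother ("child leads"). No zero padding or tapering is
#' applied; each lag simply uses its \code{n - |k|} overlapping samples.
#'
#' @param mother,child numeric residual vectors of equal length, or
#'   \code{residual_series} objects.
#' @param max_lag maximum lag, seconds (= samples at 1 Hz).
#' @param dyad_id,condition,source identifiers carried into the result.
#' @return an object of class \code{dyad_synchrony}; see [dyad_synchrony()].
#' @export
cross_correlation_profile <- function(mother, child, max_lag = 3,
                                      dyad_id = NA_character_,
                                      condition = NA_character_,
                                      source = NA_character_) {
  m <- if (inherits(mother, "residual_series")) mother$values else as.numeric(mother)
  c_ <- if (inherits(child, "residual_series")) child$values else as.numeric(child)
  if (length(m) != length(c_)) stop("residual series must have equal length")
  n <- length(m)
  if (n < 30) stop("residual series too short (need >= 30)")
  lags <- -max_lag:max_lag
  r <- rep(NA_real_, length(lags))
  n_overlap <- integer(length(lags))
  for (i in seq_along(lags)) {
    k <- lags[i]
    t0 <- max(1L, 1L - k)
    t1 <- min(n, n - k)
    mi <- m[t0:t1]
    ci <- c_[(t0 + k):(t1 + k)]
    n_overlap[i] <- t1 - t0 + 1L
    if (stats::sd(mi) > 0 && stats::sd(ci) > 0) r[i] <- stats::cor(mi, ci)
  }
  structure(list(lags = lags, r = r, n_overlap = n_overlap, n = n,
                 dyad_id = dyad_id, condition = condition, source = source),
            class = "dyad_synchrony")
}

#' Dyadic physiological synchrony between two partners
#'
#' The core estimator: computes the lagged cross-correlation synchrony
#' profile between a mother's and a child's per-second cardiac series. Each
#' partner's series is pre-whitened independently (second-order polynomial
#' detrend, then ARIMA(1,1,1) innovations) and the residuals are
#' cross-correlated at integer lags \code{-sync_lags_s .. +sync_lags_s}.
#' For RSA input only the span valid in both partners enters the pipeline;
#' for IBI the epoch-means series is used as is.
#'
#' Negative lags mean the child's series precedes the mother's.
#'
#' @param mother,child per-second series for the two partners: numeric
#'   vectors, \code{epoch_series} or \code{rsa_series} objects.
#' @param source \code{"ibi"} or \code{"rsa"} (metadata; also selects the
#'   common-valid-span rule when series carry validity masks).
#' @param config a [pipeline_config()].
#' @param dyad_id,condition identifiers carried into the result.
#' @return an object of class \code{dyad_synchrony} with elements
#'   \code{lags}, \code{r}, \code{n_overlap}, \code{prewhiten} (per-partner
#'   reports) and identifiers. Methods: \code{print}, \code{summary},
#'   \code{coef}, \code{plot}.
#' @examples
#' cfg <- sim_config(n_dyads = 1, seed = 42)
#' coh <- simulate_cohort(cfg)
#' rec <- coh$dyads$d001$La1
#' fit <- dyad_synchrony(ibi_epoch_series(rec$mother), ibi_epoch_series(rec$child))
#' coef(fit)
#' @export
dyad_synchrony <- function(mother, child, source = c("ibi", "rsa"),
                           config = pipeline_config(),
                           dyad_id = NA_character_, condition = NA_character_) {
  source <- match.arg(source)
  vm <- series_values(mother)
  vc <- series_values(child)
  nn <- min(length(vm), length(vc))
  vm <- vm[seq_len(nn)]
  vc <- vc[seq_len(nn)]
  common <- !is.na(vm) & !is.na(vc)
  if (sum(common) < 30) stop("fewer than 30 common valid seconds")
  vm[!common] <- NA
  vc[!common] <- NA
  pm <- prewhiten_series(vm, config)
  pc <- prewhiten_series(vc, config)
  prof <- cross_correlation_profile(pm, pc, config$sync_lags_s,
                                    dyad_id = dyad_id, condition = condition,
                                    source = source)
  prof$prewhiten <- list(mother = pm$report, child = pc$report)
  prof
}

series_values <- function(x) {
  if (inherits(x, c("epoch_series", "rsa_series"))) x$values else as.numeric(x)
}

#' @export
print.dyad_synchrony <- function(x, digits = 3, ...) {
  hdr <- "Dyadic synchrony profile"
  meta <- c(x$dyad_id, x$condition, x$source)
  meta <- meta[!is.na(meta)]
  if (length(meta)) hdr <- paste0(hdr, " (", paste(meta, collapse = ", "), ")")
  cat(hdr, "\n")
  tab <- format(round(x$r, digits))
  names(tab) <- sprintf("%+d", x$lags)
  print(tab, quote = FALSE)
  invisible(x)
}

#' @export
coef.dyad_synchrony <- function(object, ...) {
  stats::setNames(object$r, sprintf("lag%+d", object$lags))
}

#' @export
summary.dyad_synchrony <- function(object, ...) {
  peak <- which.max(object$r)
  out <- list(profile = object,
              r0 = object$r[object$lags == 0],
              peak_lag = object$lags[peak], peak_r = object$r[peak])
  class(out) <- "summary.dyad_synchrony"
  out
}

#' @export
print.summary.dyad_synchrony <- function(x, ...) {
  print(x$profile)
  cat(sprintf("lag-0 r = %.3f; peak r = %.3f at lag %+d s (%s)\n",
              x$r0, x$peak_r, x$peak_lag,
              if (x$peak_lag < 0) "child leads" else if (x$peak_lag > 0)
                "mother leads" else "concurrent"))
  invisible(x)
}

#' @export
plot.dyad_synchrony <- function(x, ...) {
  graphics::barplot(x$r, names.arg = sprintf("%+d", x$lags),
                    xlab = "lag (s; negative = child leads)",
                    ylab = "cross-correlation r", ...)
  graphics::abline(h = 0)
  invisible(x)
}

#' Synchrony profile of one simulated dyad record
#'
#' Convenience wrapper running the full per-dyad pipeline on one condition
#' record of a [simulate_cohort()] cohort.
#'
#' @param rec one \code{cohort$dyads[[id]][[condition]]} record.
#' @param source \code{"ibi"} or \code{"rsa"}.
#' @param config a [pipeline_config()].
#' @param ... passed to [dyad_synchrony()].
#' @return a \code{dyad_synchrony} object.
#' @export
compute_synchrony <- function(rec, source = c("ibi", "rsa"),
                              config = pipeline_config(), ...) {
  source <- match.arg(source)
  ser <- function(rp) {
    if (source == "ibi") ibi_epoch_series(rp, config) else rsa_epoch_series(rp, config)
  }
  dyad_synchrony(ser(rec$mother), ser(rec$child), source = source,
                 config = config, ...)
}
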