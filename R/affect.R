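#' Binary per-second affect series from annotation intervals
#'
#' Second \code{j} (half-open \code{[j, j+1)}) is scored 1 when the
#' positive-affect annotations cover at least \code{threshold_s} of it.
#' Annotations coded natively per second reproduce themselves exactly under
#' this rule.
#'
#' @param intervals data frame from [read_affect_annotations()] (only rows
#'   with \code{is_positive} are used), or a two-column matrix/data frame of
#'   (onset_s, offset_s).
#' @param duration_s recording duration, seconds.
#' @param threshold_s minimum coverage of a second to score it 1.
#' @return integer 0/1 vector of length \code{floor(duration_s)} with
#'   attributes \code{fraction} (mean of the binary series -- the
#'   proportion-of-task-time summary) and \code{coverage_fraction}
#'   (continuous covered time / duration).
#' @export
affect_series <- function(intervals, duration_s, threshold_s = 0.5) {
  n <- floor(duration_s)
  if (is.data.frame(intervals) && "is_positive" %in% names(intervals)) {
    intervals <- intervals[intervals$is_positive, c("onset_s", "offset_s"), drop = FALSE]
  }
  intervals <- as.data.frame(intervals)
  out <- integer(n)
  covered <- 0
  if (nrow(intervals)) {
    names(intervals)[1:2] <- c("onset_s", "offset_s")
    on <- pmax(intervals$onset_s, 0)
    off <- pmin(intervals$offset_s, duration_s)
    keep <- off > on
    on <- on[keep]; off <- off[keep]
    # merge overlaps so coverage is not double counted
    o <- order(on)
    on <- on[o]; off <- off[o]
    merged_on <- c(); merged_off <- c()
    for (i in seq_along(on)) {
      if (length(merged_on) && on[i] <= merged_off[length(merged_off)]) {
        merged_off[length(merged_off)] <- max(merged_off[length(merged_off)], off[i])
      } else {
        merged_on <- c(merged_on, on[i]); merged_off <- c(merged_off, off[i])
      }
    }
    covered <- sum(merged_off - merged_on)
    for (i in seq_along(merged_on)) {
      j0 <- floor(merged_on[i]); j1 <- min(ceiling(merged_off[i]), n) - 1
      for (j in j0:j1) {
        cov_j <- min(merged_off[i], j + 1) - max(merged_on[i], j)
        if (cov_j >= threshold_s - 1e-9) out[j + 1] <- 1L
      }
    }
  }
  attr(out, "fraction") <- mean(out)
  attr(out, "coverage_fraction") <- covered / duration_s
  out
}

#' Shared (dyadic) affect series
#'
#' Elementwise AND of the mother's and child's binary series: 1 only when
#' both partners show positive affect in the same second.
#'
#' @param mother,child binary 0/1 vectors on the same grid.
#' @return integer 0/1 vector with a \code{fraction} attribute.
#' @export
shared_affect <- function(mother, child) {
  stopifnot(length(mother) == length(child))
  out <- as.integer(mother == 1L & child == 1L)
  attr(out, "fraction") <- mean(out)
  out
}

#' Lagged binary-affect design matrix
#'
#' One predictor column per shift \code{s} in \code{-max_lag .. +max_lag};
#' column \code{s} holds \code{affect[t - s]} so positive shifts put
#' behaviour ahead of the physiological response (behaviour leading) and
#' negative shifts behind it. Out-of-range entries are 0 (absence of affect
#' is meaningful for a binary predictor), preserving the series length.
#'
#' @param affect binary 0/1 vector.
#' @param max_lag maximum shift, seconds.
#' @return an \code{n x (2 max_lag + 1)} matrix with columns named by shift.
#' @export
lagged_affect_design <- function(affect, max_lag = 10) {
  n <- length(affect)
  if (n <= 2 * max_lag + 3) stop("series too short for the lag range")
  shifts <- -max_lag:max_lag
  X <- matrix(0, n, length(shifts),
              dimnames = list(NULL, sprintf("s%+d", shifts)))
  for (i in seq_along(shifts)) {
    s <- shifts[i]
    t <- seq_len(n)
    src <- t - s
    ok <- src >= 1 & src <= n
    X[t[ok], i] <- affect[src[ok]]
  }
  X
}

#' Regress lagged affect out of a cardiac series
#'
#' Least-squares regression of the participant's raw per-second series on
#' all \code{2 max_lag + 1} lagged copies of the affect series jointly
#' (plus an intercept); the residuals re-enter the synchrony pipeline
#' unchanged in length (NAs preserved). Removing the predictors at every
#' shift removes the influence of affect on the signal regardless of their
#' temporal alignment. An all-zero affect series is a no-op: the input is
#' returned exactly. Collinear columns are dropped by the fit (rank
#' handling of \code{lm.fit}).
#'
#' @param ans numeric per-second series (NAs allowed).
#' @param affect binary 0/1 vector on the same grid: the participant's own
#'   series (individual variant) or the dyad's shared series.
#' @param max_lag maximum shift, seconds.
#' @return numeric vector, same length as \code{ans}, with attribute
#'   \code{r_squared} (variance of \code{ans} explained by the affect
#'   design).
#' @export
regress_out_affect <- function(ans, affect, max_lag = 10) {
  n <- length(ans)
  affect <- as.integer(affect[seq_len(min(length(affect), n))])
  affect <- c(affect, integer(n - length(affect)))
  if (all(affect == 0L)) {
    out <- ans
    attr(out, "r_squared") <- 0
    return(out)
  }
  X <- cbind(`(Intercept)` = 1, lagged_affect_design(affect, max_lag))
  idx <- which(!is.na(ans))
  y <- ans[idx]
  fit <- stats::lm.fit(X[idx, , drop = FALSE], y)
  out <- rep(NA_real_, n)
  out[idx] <- fit$residuals
  attr(out, "r_squared") <- 1 - stats::var(fit$residuals) / stats::var(y)
  out
}

#' Affect-cleaned synchrony for one dyad
#'
#' Removes lagged affect from both partners' raw per-second cardiac series
#' (before detrending, so the downstream pipeline is identical for cleaned
#' and uncleaned branches), recomputes the synchrony profile, and reports
#' the per-lag reduction. Variant \code{"individual"} regresses each
#' partner's own affect out of their own series; \code{"shared"} uses the
#' dyad's shared (AND) series for both partners.
#'
#' @param mother_series,child_series per-second cardiac series (numeric,
#'   \code{epoch_series} or \code{rsa_series}).
#' @param mother_affect,child_affect binary 0/1 vectors.
#' @param variant \code{"individual"} or \code{"shared"}.
#' @param source \code{"ibi"} or \code{"rsa"} (metadata).
#' @param config a [pipeline_config()].
#' @param dyad_id,condition identifiers.
#' @return an object of class \code{cleaning_result}: list with
#'   \code{variant}, \code{uncleaned}/\code{cleaned} \code{dyad_synchrony}
#'   profiles, \code{delta} (uncleaned - cleaned per lag) and
#'   \code{r_squared} per partner.
#' @export
clean_synchrony <- function(mother_series, child_series,
                            mother_affect, child_affect,
                            variant = c("individual", "shared"),
                            source = "ibi", config = pipeline_config(),
                            dyad_id = NA_character_, condition = NA_character_) {
  variant <- match.arg(variant)
  vm <- series_values(mother_series)
  vc <- series_values(child_series)
  if (variant == "shared") {
    sh <- shared_affect(mother_affect[seq_len(min(length(mother_affect), length(child_affect)))],
                        child_affect[seq_len(min(length(mother_affect), length(child_affect)))])
    am <- sh; ac <- sh
  } else {
    am <- mother_affect; ac <- child_affect
  }
  unc <- dyad_synchrony(vm, vc, source = source, config = config,
                        dyad_id = dyad_id, condition = condition)
  cl <- cleaned_profile(vm, vc, am, ac, source, config, dyad_id, condition)
  cm <- cl$cm; cc <- cl$cc; cln <- cl$profile
  structure(list(variant = variant, uncleaned = unc, cleaned = cln,
                 delta = unc$r - cln$r, lags = unc$lags,
                 r_squared = c(mother = attr(cm, "r_squared"),
                               child = attr(cc, "r_squared"))),
            class = "cleaning_result")
}

#' @export
print.cleaning_result <- function(x, ...) {
  cat(sprintf("Affect cleaning (%s): mean delta r = %.4f (positive = synchrony reduced)\n",
              x$variant, mean(x$delta, na.rm = TRUE)))
  tab <- rbind(uncleaned = x$uncleaned$r, cleaned = x$cleaned$r, delta = x$delta)
  colnames(tab) <- sprintf("%+d", x$lags)
  print(round(tab, 3))
  invisible(x)
}

# regress affect out of both raw series and rerun the synchrony pipeline
cleaned_profile <- function(vm, vc, affect_m, affect_c, source, config,
                            dyad_id = NA_character_, condition = NA_character_) {
  cm <- regress_out_affect(vm, affect_m, config$clean_lags_s)
  cc <- regress_out_affect(vc, affect_c, config$clean_lags_s)
  prof <- dyad_synchrony(as.numeric(cm), as.numeric(cc), source = source,
                         config = config, dyad_id = dyad_id,
                         condition = condition)
  list(cm = cm, cc = cc, profile = prof)
}

#' Shuffled-affect control for one dyad
#'
#' Re-runs affect cleaning replacing each partner's affect series with the
#' same-role series of every other dyad in turn (child cleaned with other
#' children's affect, mother with other mothers'), and averages the cleaned
#' profiles. The contrast between own-affect cleaning and this control
#' separates a genuine affect contribution from a generic variance-removal
#' artefact of regressing 21 predictors out.
#'
#' @param cohort a \code{dyad_cohort} (or compatible list of records).
#' @param dyad_id the target dyad.
#' @param condition the condition (must have coded affect).
#' @param variant \code{"individual"} or \code{"shared"}.
#' @param source \code{"ibi"} or \code{"rsa"}.
#' @param config a [pipeline_config()].
#' @return list with \code{mean_cleaned_r} (per lag), \code{mean_delta},
#'   \code{lags}, \code{set_size}.
#' @export
shuffled_affect_control <- function(cohort, dyad_id, condition,
                                    variant = c("individual", "shared"),
                                    source = "ibi", config = pipeline_config()) {
  variant <- match.arg(variant)
  others <- setdiff(names(cohort$dyads), dyad_id)
  others <- Filter(function(j) has_affect(cohort$dyads[[j]][[condition]]), others)
  if (!length(others)) stop("no other dyads with affect data in ", condition)
  rec <- cohort$dyads[[dyad_id]][[condition]]
  ser <- dyad_series(rec, source, config)
  vm <- series_values(ser$mother)
  vc <- series_values(ser$child)
  unc <- dyad_synchrony(vm, vc, source = source, config = config,
                        dyad_id = dyad_id, condition = condition)
  acc <- 0
  for (j in others) {
    aff_j <- cohort$dyads[[j]][[condition]]$affect
    if (variant == "shared") {
      sh <- shared_affect(aff_j$mother, aff_j$child)
      am <- sh; ac <- sh
    } else {
      am <- aff_j$mother; ac <- aff_j$child
    }
    acc <- acc + cleaned_profile(vm, vc, am, ac, source, config)$profile$r
  }
  mean_cleaned <- acc / length(others)
  list(mean_cleaned_r = mean_cleaned, mean_delta = unc$r - mean_cleaned,
       lags = unc$lags, set_size = length(others))
}

has_affect <- function(rec) {
  isTRUE(rec$affect_coded) && !is.null(rec$affect) &&
    (any(rec$affect$mother == 1L) || any(rec$affect$child == 1L))
}

dyad_series <- function(rec, source, config) {
  f <- if (source == "ibi") ibi_epoch_series else rsa_epoch_series
  list(mother = f(rec$mother, config), child = f(rec$child, config))
}
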