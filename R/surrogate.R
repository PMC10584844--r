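#' Pre-whitened residual series for every participant in a cohort
#'
#' Computes, once per participant and condition, the per-second series
#' (IBI epoch means or RSA) and its pre-whitened residuals. Surrogate
#' construction correlates many cross-dyad pairs, so caching the residuals
#' avoids refitting the same ARIMA models for every pairing. Participants
#' whose series fail any stage are recorded as excluded, not imputed.
#'
#' @param cohort a \code{dyad_cohort} (from [simulate_cohort()] or
#'   [cohort_from_manifest()]).
#' @param source \code{"ibi"} or \code{"rsa"}.
#' @param config a [pipeline_config()].
#' @return list with \code{residuals[[dyad_id]][[condition]]$mother/child}
#'   numeric vectors and \code{excluded}, a data frame of failed
#'   (dyad, condition) entries with the error message.
#' @export
cohort_residuals <- function(cohort, source = c("ibi", "rsa"),
                             config = pipeline_config()) {
  source <- match.arg(source)
  res <- list()
  excl <- list()
  for (id in names(cohort$dyads)) {
    res[[id]] <- list()
    for (cond in names(cohort$dyads[[id]])) {
      rec <- cohort$dyads[[id]][[cond]]
      r <- tryCatch({
        ser <- dyad_series(rec, source, config)
        list(mother = prewhiten_series(series_values(ser$mother), config)$values,
             child = prewhiten_series(series_values(ser$child), config)$values)
      }, error = function(e) e)
      if (inherits(r, "error")) {
        excl[[length(excl) + 1L]] <- data.frame(dyad_id = id, condition = cond,
                                                error = conditionMessage(r))
      } else {
        res[[id]][[cond]] <- r
      }
    }
  }
  list(residuals = res,
       excluded = if (length(excl)) do.call(rbind, excl)
                  else data.frame(dyad_id = character(), condition = character(),
                                  error = character()))
}

#' Shuffled-pair surrogate synchrony for one dyad
#'
#' Builds the dyad- and condition-specific surrogate: the dyad's child is
#' cross-correlated with every other dyad's mother in the same condition,
#' and the dyad's mother with every other dyad's child, and the resulting
#' profiles are averaged per lag (arithmetic mean of correlations over the
#' pooled set). The set is exhaustive -- all permuted partners -- so the
#' result is deterministic; a participant is never paired with their own
#' partner. Pairings with a missing series are skipped and reduce
#' \code{set_size}. Series of unequal residual length are truncated from
#' the start to the shorter length.
#'
#' @param cohort a \code{dyad_cohort}.
#' @param dyad_id target dyad identifier.
#' @param condition condition label.
#' @param source \code{"ibi"} or \code{"rsa"}.
#' @param config a [pipeline_config()].
#' @param cache optional result of [cohort_residuals()] for this source.
#' @return an object of class \code{surrogate_result}: list with
#'   \code{mean_r} per lag, \code{lags}, \code{set_size}, identifiers.
#' @export
shuffled_pair_profiles <- function(cohort, dyad_id, condition,
                                   source = c("ibi", "rsa"),
                                   config = pipeline_config(), cache = NULL) {
  source <- match.arg(source)
  if (is.null(cache)) cache <- cohort_residuals(cohort, source, config)
  res <- cache$residuals
  if (is.null(res[[dyad_id]][[condition]])) {
    stop("no valid data for dyad ", dyad_id, " in ", condition)
  }
  own <- res[[dyad_id]][[condition]]
  others <- setdiff(names(res), dyad_id)
  acc <- NULL
  set_size <- 0L
  for (j in others) {
    other <- res[[j]][[condition]]
    if (is.null(other)) next
    for (pair in list(list(m = other$mother, c = own$child),
                      list(m = own$mother, c = other$child))) {
      nn <- min(length(pair$m), length(pair$c))
      if (nn < 30) next
      prof <- cross_correlation_profile(pair$m[seq_len(nn)], pair$c[seq_len(nn)],
                                        config$sync_lags_s)
      acc <- if (is.null(acc)) prof$r else acc + prof$r
      set_size <- set_size + 1L
    }
  }
  if (set_size == 0L) stop("surrogate set empty for dyad ", dyad_id, " in ", condition)
  structure(list(mean_r = acc / set_size, lags = -config$sync_lags_s:config$sync_lags_s,
                 set_size = set_size, dyad_id = dyad_id, condition = condition,
                 source = source),
            class = "surrogate_result")
}

#' @export
print.surrogate_result <- function(x, ...) {
  cat(sprintf("Shuffled-pair surrogate (%s, %s, %s): %d pairings\n",
              x$dyad_id, x$condition, x$source, x$set_size))
  tab <- round(x$mean_r, 3)
  names(tab) <- sprintf("%+d", x$lags)
  print(tab)
  invisible(x)
}

#' Actual and surrogate synchrony for a whole cohort
#'
#' Computes, for every dyad and condition with valid data, the actual
#' synchrony profile and the exhaustive shuffled-pair surrogate mean, in
#' long format (one row per dyad, condition, lag). Dyads excluded at the
#' residual stage are listed in the \code{excluded} attribute.
#'
#' @param cohort a \code{dyad_cohort}.
#' @param source \code{"ibi"} or \code{"rsa"}.
#' @param config a [pipeline_config()].
#' @param conditions_use subset of conditions (default: all present).
#' @return data frame with columns \code{dyad_id}, \code{condition},
#'   \code{source}, \code{lag_s}, \code{r_actual}, \code{r_surrogate},
#'   \code{surrogate_set_size}.
#' @export
cohort_synchrony <- function(cohort, source = c("ibi", "rsa"),
                             config = pipeline_config(),
                             conditions_use = NULL) {
  source <- match.arg(source)
  cache <- cohort_residuals(cohort, source, config)
  res <- cache$residuals
  conds <- conditions_use %||% unique(unlist(lapply(res, names)))
  rows <- list()
  for (id in names(res)) {
    for (cond in intersect(conds, names(res[[id]]))) {
      own <- res[[id]][[cond]]
      nn <- min(length(own$mother), length(own$child))
      act <- cross_correlation_profile(own$mother[seq_len(nn)],
                                       own$child[seq_len(nn)],
                                       config$sync_lags_s)
      sur <- tryCatch(
        shuffled_pair_profiles(cohort, id, cond, source, config, cache),
        error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        dyad_id = id, condition = cond, source = source, lag_s = act$lags,
        r_actual = act$r,
        r_surrogate = if (is.null(sur)) NA_real_ else sur$mean_r,
        surrogate_set_size = if (is.null(sur)) 0L else sur$set_size)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "excluded") <- cache$excluded
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
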