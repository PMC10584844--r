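#' Read an R-peak series from CSV
#'
#' The file must contain a column \code{t_rpeak_s} of nondecreasing,
#' nonnegative R-peak times in seconds from recording start. Duplicate times
#' are collapsed. An optional constant \code{duration_s} column declares the
#' recording duration; otherwise the last peak time is used.
#'
#' @param path path to a CSV file.
#' @return an object of class \code{rpeaks}: list with \code{times_s}
#'   (strictly increasing), \code{duration_s} and \code{n}.
#' @seealso [rpeaks()] for constructing a series in code.
#' @export
read_rpeaks <- function(path) {
  if (!file.exists(path)) stop("R-peak file not found: ", path)
  df <- utils::read.csv(path)
  if (!"t_rpeak_s" %in% names(df)) {
    stop("R-peak CSV must have a 't_rpeak_s' column: ", path)
  }
  t <- as.numeric(df$t_rpeak_s)
  if (anyNA(t) || any(t < 0)) stop("R-peak times must be nonnegative numbers: ", path)
  dur <- if ("duration_s" %in% names(df)) as.numeric(df$duration_s[1]) else NULL
  rpeaks(t, duration_s = dur)
}

#' Construct an R-peak series
#'
#' @param times_s nondecreasing nonnegative peak times, seconds. Duplicates
#'   are collapsed; a decrease after collapsing is an error.
#' @param duration_s recording duration; defaults to the last peak time.
#' @return an object of class \code{rpeaks}.
#' @export
rpeaks <- function(times_s, duration_s = NULL) {
  t <- unique(as.numeric(times_s))
  if (is.unsorted(t, strictly = TRUE)) {
    stop("R-peak times must be nondecreasing (after collapsing duplicates)")
  }
  if (length(t) < 3L) stop("insufficient data: need at least 3 R-peaks")
  if (is.null(duration_s)) duration_s <- t[length(t)]
  if (t[length(t)] > duration_s + 1e-9) stop("R-peak times exceed declared duration")
  structure(list(times_s = t, duration_s = duration_s, n = length(t)),
            class = "rpeaks")
}

#' @export
print.rpeaks <- function(x, ...) {
  ibi <- diff(x$times_s) * 1000
  cat(sprintf("R-peak series: %d peaks over %.1f s (mean IBI %.1f ms)\n",
              x$n, x$duration_s, mean(ibi)))
  invisible(x)
}

#' Interbeat intervals of an R-peak series
#'
#' @param x an \code{rpeaks} object.
#' @return numeric vector of interbeat intervals, milliseconds.
#' @export
ibi_ms <- function(x) {
  stopifnot(inherits(x, "rpeaks"))
  diff(x$times_s) * 1000
}

#' Read behavioural annotation intervals
#'
#' Reads a CSV with columns \code{code}, \code{onset_s}, \code{offset_s}.
#' Intervals of the \code{"positive"} code are the ones used downstream;
#' other codes are retained and flagged via the \code{is_positive} column.
#' Intervals running past \code{duration_s} are clipped with a warning; a
#' negative onset is an error. An empty file yields an empty data frame
#' (participant showed no coded affect).
#'
#' @param path path to the annotation CSV.
#' @param duration_s recording duration used for clipping.
#' @return data frame with columns \code{code}, \code{onset_s},
#'   \code{offset_s}, \code{is_positive}.
#' @export
read_affect_annotations <- function(path, duration_s) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.csv(path, colClasses = c(code = "character"))
  need <- c("code", "onset_s", "offset_s")
  if (!all(need %in% names(df))) {
    stop("annotation CSV must have columns code, onset_s, offset_s: ", path)
  }
  if (nrow(df) == 0L) {
    return(data.frame(code = character(), onset_s = numeric(),
                      offset_s = numeric(), is_positive = logical()))
  }
  if (any(df$onset_s < 0)) stop("negative annotation onset in ", path)
  if (any(df$offset_s <= df$onset_s)) stop("annotation offset must exceed onset in ", path)
  over <- df$offset_s > duration_s
  if (any(over)) {
    warning(sprintf("%d annotation interval(s) clipped to duration %.1f s",
                    sum(over), duration_s))
    df$offset_s[over] <- duration_s
    df <- df[df$offset_s > df$onset_s, , drop = FALSE]
  }
  df$is_positive <- df$code == "positive"
  df[order(df$onset_s), , drop = FALSE]
}

#' Read a cohort manifest
#'
#' A manifest links each participant recording to its dyad, role and task
#' condition: columns \code{dyad_id}, \code{role} (mother/child),
#' \code{condition} (Rest/Single/La1/La2), \code{rpeak_path} and optional
#' \code{affect_path}. Paths are resolved relative to the manifest file.
#' Each (dyad, role, condition) may appear at most once and every referenced
#' file must exist.
#'
#' @param path manifest CSV path.
#' @return data frame of manifest entries with resolved paths.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("dyad_id", "role", "condition", "rpeak_path")
  if (!all(need %in% names(df))) {
    stop("manifest must have columns dyad_id, role, condition, rpeak_path")
  }
  if (!"affect_path" %in% names(df)) df$affect_path <- NA_character_
  df$affect_path[!nzchar(df$affect_path) | is.na(df$affect_path)] <- NA_character_
  bad_role <- setdiff(unique(df$role), c("mother", "child"))
  if (length(bad_role)) stop("unknown role(s): ", paste(bad_role, collapse = ", "))
  bad_cond <- setdiff(unique(df$condition), conditions())
  if (length(bad_cond)) stop("unknown condition(s): ", paste(bad_cond, collapse = ", "))
  key <- paste(df$dyad_id, df$role, df$condition)
  if (anyDuplicated(key)) stop("duplicate (dyad_id, role, condition) in manifest")
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(is.na(p) | grepl("^/", p), p, file.path(base, p))
  df$rpeak_path <- resolve(df$rpeak_path)
  df$affect_path <- resolve(df$affect_path)
  missing <- df$rpeak_path[!file.exists(df$rpeak_path)]
  if (length(missing)) stop("missing R-peak file(s): ", paste(missing, collapse = ", "))
  aff <- df$affect_path[!is.na(df$affect_path)]
  if (any(!file.exists(aff))) stop("missing affect file(s)")
  df
}

#' Task conditions
#'
#' The four task conditions in the study design: a joint rest video
#' (\code{Rest}), the labyrinth game played alone (\code{Single}) and the two
#' joint labyrinth games (\code{La1}, \code{La2}). Coupling between partners
#' is expected only in the interactive games.
#'
#' @return character vector of condition labels.
#' @export
conditions <- function() c("Rest", "Single", "La1", "La2")

#' Analysis pipeline configuration
#'
#' All tunable parameters of the analysis with their defaults: the 10 Hz
#' IBI resampling and 1-s epoch means, the 4 Hz spline grid, 32-s/31-s
#' overlap spectral windows over the 0.12-0.40 Hz respiration band for RSA,
#' synchrony lags -3..+3 s, affect-cleaning lags -10..+10 s, second-order
#' detrending and ARIMA(1,1,1) pre-whitening, and the FDR level.
#'
#' @param epoch_s epoch length, seconds.
#' @param resample_hz IBI resampling rate before epoch averaging, Hz.
#' @param rsa_interp_hz spline interpolation rate for RSA, Hz.
#' @param rsa_window_s spectral window length, seconds.
#' @param rsa_overlap_s window overlap, seconds (must be < window).
#' @param rsa_band_hz length-2 numeric, respiration band (low, high), Hz.
#' @param rsa_nw time-bandwidth product of the Slepian taper bank.
#' @param rsa_k number of tapers.
#' @param sync_lags_s maximum synchrony lag, seconds (profile spans
#'   \code{-sync_lags_s..+sync_lags_s}).
#' @param clean_lags_s maximum affect-cleaning lag, seconds.
#' @param arima_order length-3 integer (p, d, q).
#' @param detrend_order polynomial detrend order.
#' @param fdr_alpha FDR level for adjusted p values.
#' @param seed integer seed recorded with pipeline output.
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(epoch_s = 1, resample_hz = 10, rsa_interp_hz = 4,
                            rsa_window_s = 32, rsa_overlap_s = 31,
                            rsa_band_hz = c(0.12, 0.40),
                            rsa_nw = 2.5, rsa_k = 3,
                            sync_lags_s = 3, clean_lags_s = 10,
                            arima_order = c(1, 1, 1), detrend_order = 2,
                            fdr_alpha = 0.05, seed = 1L) {
  cfg <- list(epoch_s = epoch_s, resample_hz = resample_hz,
              rsa_interp_hz = rsa_interp_hz, rsa_window_s = rsa_window_s,
              rsa_overlap_s = rsa_overlap_s, rsa_band_hz = rsa_band_hz,
              rsa_nw = rsa_nw, rsa_k = rsa_k,
              sync_lags_s = as.integer(sync_lags_s),
              clean_lags_s = as.integer(clean_lags_s),
              arima_order = as.integer(arima_order),
              detrend_order = as.integer(detrend_order),
              fdr_alpha = fdr_alpha, seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  b <- cfg$rsa_band_hz
  if (!(b[1] > 0 && b[1] < b[2] && b[2] < cfg$rsa_interp_hz / 2)) {
    stop("band must satisfy 0 < low < high < rsa_interp_hz/2")
  }
  if (cfg$rsa_overlap_s >= cfg$rsa_window_s) stop("overlap must be < window")
  if (cfg$sync_lags_s < 1 || cfg$clean_lags_s < 1) stop("lag ranges must be positive")
  if (length(cfg$arima_order) != 3) stop("arima_order must be length 3")
  invisible(cfg)
}

#' Load a pipeline configuration from a YAML file
#'
#' The file is one flat document; every default of [pipeline_config()] may be
#' overridden. Unknown keys are an error so typos do not pass silently.
#'
#' @param path YAML file path.
#' @return a \code{pipeline_config}.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' Write a pipeline configuration to YAML
#'
#' @param cfg a \code{pipeline_config}.
#' @param path output path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Write an R-peak series to CSV
#'
#' @param x an \code{rpeaks} object.
#' @param path output path.
#' @export
write_rpeaks <- function(x, path) {
  stopifnot(inherits(x, "rpeaks"))
  utils::write.csv(data.frame(t_rpeak_s = x$times_s, duration_s = x$duration_s),
                   path, row.names = FALSE)
  invisible(path)
}

# Per-second series (epoch means, RSA, affect) share one on-disk shape:
# t_s, value, valid.
write_series_csv <- function(values, valid, path, start_s = 0) {
  utils::write.csv(data.frame(t_s = start_s + seq_along(values) - 1,
                              value = values, valid = as.integer(valid)),
                   path, row.names = FALSE)
  invisible(path)
}

read_series_csv <- function(path) {
  df <- utils::read.csv(path)
  list(values = df$value, valid = df$valid == 1L, start_s = df$t_s[1])
}
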