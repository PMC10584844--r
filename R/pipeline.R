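log_msg <- function(level, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  level, paste0(...)))
}

#' Load a cohort from a manifest of recordings
#'
#' Reads every R-peak and affect file referenced by the manifest and
#' assembles the same in-memory structure [simulate_cohort()] produces, so
#' recorded and simulated cohorts flow through identical code. A
#' participant file that fails to load excludes that (dyad, condition) with
#' a logged warning; the dyad may still contribute other conditions.
#'
#' @param manifest data frame from [read_manifest()], or a manifest path.
#' @return a \code{dyad_cohort} (without ground truth).
#' @export
cohort_from_manifest <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  dyads <- list()
  for (id in unique(manifest$dyad_id)) {
    sub <- manifest[manifest$dyad_id == id, , drop = FALSE]
    conds <- list()
    for (cond in unique(sub$condition)) {
      rows <- sub[sub$condition == cond, , drop = FALSE]
      if (!all(c("mother", "child") %in% rows$role)) {
        log_msg("WARN", sprintf("dyad %s/%s: missing a role, excluded", id, cond))
        next
      }
      rec <- tryCatch({
        out <- list()
        aff <- list()
        coded <- FALSE
        for (role in c("mother", "child")) {
          row <- rows[rows$role == role, ][1, ]
          rp <- read_rpeaks(row$rpeak_path)
          out[[role]] <- rp
          if (!is.na(row$affect_path)) {
            iv <- read_affect_annotations(row$affect_path, rp$duration_s)
            aff[[role]] <- affect_series(iv, rp$duration_s)
            coded <- TRUE
          }
        }
        if (!coded) {
          n <- floor(min(out$mother$duration_s, out$child$duration_s))
          aff <- list(mother = integer(n), child = integer(n))
        } else {
          for (role in c("mother", "child")) {
            if (is.null(aff[[role]])) {
              aff[[role]] <- integer(floor(out[[role]]$duration_s))
            }
          }
        }
        c(out, list(affect = aff, affect_coded = coded))
      }, error = function(e) e)
      if (inherits(rec, "error")) {
        log_msg("WARN", sprintf("dyad %s/%s excluded: %s", id, cond,
                                conditionMessage(rec)))
      } else {
        conds[[cond]] <- rec
      }
    }
    if (length(conds)) dyads[[id]] <- conds
  }
  structure(list(dyads = dyads, ground_truth = NULL, config = NULL),
            class = "dyad_cohort")
}

#' Run the full synchrony pipeline on a cohort
#'
#' Executes every stage for each requested signal: per-second series,
#' pre-whitening, actual and shuffled-pair surrogate synchrony profiles,
#' affect cleaning (individual and shared variants, where affect is coded),
#' and the group statistics (actual-vs-surrogate paired t tests with FDR
#' across lags per condition and measure, mirrored-lag tests, and condition
#' mixed models per lag). Results are written as CSV files under
#' \code{out_dir} along with the echoed configuration and a run log. A
#' failing (dyad, condition) is excluded from group statistics with a
#' logged warning, never imputed.
#'
#' @param cohort a \code{dyad_cohort}, or a manifest path/data frame.
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed), or \code{NULL} to
#'   skip writing.
#' @param signals subset of \code{c("ibi", "rsa")}.
#' @param run_lmm fit the condition mixed models (needs >= 2 conditions
#'   with >= 3 dyads).
#' @return invisibly, a list with \code{profiles} (long data frame of
#'   actual + surrogate r), \code{cleaning}, \code{tests}
#'   (actual-vs-surrogate), \code{lag_signs}, \code{lmm}, \code{excluded}.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), out_dir = NULL,
                         signals = c("ibi", "rsa"), run_lmm = TRUE) {
  if (!inherits(cohort, "dyad_cohort")) cohort <- cohort_from_manifest(cohort)
  set.seed(config$seed)
  profiles <- list(); cleaning <- list(); tests <- list()
  lag_signs <- list(); lmms <- list(); excluded <- list()
  for (src in signals) {
    log_msg("INFO", "computing ", src, " synchrony profiles and surrogates")
    tab <- cohort_synchrony(cohort, src, config)
    profiles[[src]] <- tab
    excluded[[src]] <- attr(tab, "excluded")

    for (cond in unique(tab$condition)) {
      sub <- tab[tab$condition == cond, ]
      fam <- paste("actual-vs-surrogate", cond, src, sep = "/")
      res <- lapply(sort(unique(sub$lag_s)), function(k) {
        sk <- sub[sub$lag_s == k, ]
        tt <- tryCatch(paired_t(sk$r_actual, sk$r_surrogate, family_id = fam),
                       error = function(e) NULL)
        if (is.null(tt)) return(NULL)
        data.frame(condition = cond, source = src, lag_s = k, t = tt$t,
                   df = tt$df, p = tt$p, d = tt$d, n = tt$n, family_id = fam)
      })
      res <- do.call(rbind, res)
      if (!is.null(res)) {
        res$p_adj <- fdr_adjust(res$p, fam)
        tests[[paste(src, cond)]] <- res
      }
      # mirrored-lag family
      wide <- stats::reshape(sub[, c("dyad_id", "lag_s", "r_actual")],
                             idvar = "dyad_id", timevar = "lag_s",
                             direction = "wide")
      mat <- as.matrix(wide[, -1, drop = FALSE])
      colnames(mat) <- sprintf("%+d", as.integer(sub("r_actual\\.", "",
                                                     colnames(wide)[-1])))
      ls_ <- tryCatch(compare_lag_signs(mat, paste("lag-signs", cond, src, sep = "/")),
                      error = function(e) NULL)
      if (!is.null(ls_)) {
        ls_$condition <- cond; ls_$source <- src
        lag_signs[[paste(src, cond)]] <- ls_
      }
    }

    if (run_lmm && length(unique(tab$condition)) >= 2) {
      log_msg("INFO", "fitting condition mixed models (", src, ")")
      lmm_rows <- lapply(sort(unique(tab$lag_s)), function(k) {
        sk <- tab[tab$lag_s == k, ]
        fit <- tryCatch(condition_lmm(data.frame(dyad_id = sk$dyad_id,
                                                 condition = sk$condition,
                                                 value = sk$r_actual)),
                        error = function(e) NULL)
        if (is.null(fit)) return(NULL)
        data.frame(source = src, lag_s = k, F = fit$F, df_num = fit$df_num,
                   df_den = fit$df_den, p = fit$p,
                   r_squared_marginal = fit$r_squared_marginal,
                   singular = fit$singular)
      })
      lmm_tab <- do.call(rbind, lmm_rows)
      if (!is.null(lmm_tab)) {
        lmm_tab$p_adj <- fdr_adjust(lmm_tab$p, paste("lmm-lags", src, sep = "/"))
        lmms[[src]] <- lmm_tab
      }
    }

    # affect cleaning for conditions with coded affect
    for (id in names(cohort$dyads)) {
      for (cond in names(cohort$dyads[[id]])) {
        rec <- cohort$dyads[[id]][[cond]]
        if (!has_affect(rec)) next
        cl <- tryCatch({
          ser <- dyad_series(rec, src, config)
          lapply(c("individual", "shared"), function(variant) {
            cr <- clean_synchrony(ser$mother, ser$child, rec$affect$mother,
                                  rec$affect$child, variant = variant,
                                  source = src, config = config,
                                  dyad_id = id, condition = cond)
            data.frame(dyad_id = id, condition = cond, source = src,
                       variant = variant, lag_s = cr$lags,
                       r_uncleaned = cr$uncleaned$r, r_cleaned = cr$cleaned$r,
                       delta = cr$delta)
          })
        }, error = function(e) {
          log_msg("WARN", sprintf("cleaning failed for %s/%s: %s", id, cond,
                                  conditionMessage(e)))
          NULL
        })
        if (!is.null(cl)) cleaning[[paste(src, id, cond)]] <- do.call(rbind, cl)
      }
    }
  }

  out <- list(profiles = do.call(rbind, profiles),
              cleaning = if (length(cleaning)) do.call(rbind, cleaning) else NULL,
              tests = if (length(tests)) do.call(rbind, tests) else NULL,
              lag_signs = if (length(lag_signs)) do.call(rbind, lag_signs) else NULL,
              lmm = if (length(lmms)) do.call(rbind, lmms) else NULL,
              excluded = do.call(rbind, excluded),
              config = config)
  rownames(out$profiles) <- NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out$profiles, file.path(out_dir, "synchrony_profiles.csv"),
                     row.names = FALSE)
    for (nm in c("cleaning", "tests", "lag_signs", "lmm", "excluded")) {
      if (!is.null(out[[nm]]) && nrow(out[[nm]])) {
        utils::write.csv(out[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                         row.names = FALSE)
      }
    }
    write_config(config, file.path(out_dir, "config_echo.yaml"))
    writeLines(c(sprintf("run completed %s", format(Sys.time())),
                 sprintf("seed %d", config$seed),
                 sprintf("signals: %s", paste(signals, collapse = ", ")),
                 sprintf("dyads: %d", length(cohort$dyads)),
                 sprintf("excluded: %d", if (is.null(out$excluded)) 0L
                         else nrow(out$excluded))),
               file.path(out_dir, "run_log.txt"))
    log_msg("INFO", "results written to ", out_dir)
  }
  invisible(out)
}
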