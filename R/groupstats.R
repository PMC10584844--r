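#' Dependent-samples t test with effect size
#'
#' Classical paired t test on per-dyad value pairs with listwise deletion of
#' incomplete pairs, two-sided p, and the paired effect size
#' \code{d = mean(diff) / sd(diff)} (d_z; \code{d_av}, the mean difference
#' over the average of the two SDs, is available via \code{d_formula}). A
#' zero-variance difference is degenerate: no p is computed unless all
#' differences are exactly zero, in which case \code{t = 0, p = 1}.
#'
#' @param x,y numeric vectors of paired per-dyad values.
#' @param family_id label of the FDR correction family this test belongs to.
#' @param d_formula \code{"d_z"} or \code{"d_av"}.
#' @return an object of class \code{paired_test}: list with \code{t},
#'   \code{df}, \code{p}, \code{p_adj} (NA until [fdr_adjust()] is applied),
#'   \code{d}, \code{n}, \code{family_id}, \code{degenerate}.
#' @export
paired_t <- function(x, y, family_id = NA_character_,
                     d_formula = c("d_z", "d_av")) {
  d_formula <- match.arg(d_formula)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  diffs <- x - y
  sdd <- stats::sd(diffs)
  if (sdd == 0) {
    degen <- TRUE
    t_ <- 0; p <- if (all(diffs == 0)) 1 else NA_real_
    d <- NA_real_
  } else {
    degen <- FALSE
    ht <- stats::t.test(x, y, paired = TRUE)
    t_ <- unname(ht$statistic); p <- ht$p.value
    d <- if (d_formula == "d_z") mean(diffs) / sdd
         else mean(diffs) / mean(c(stats::sd(x), stats::sd(y)))
  }
  structure(list(t = t_, df = n - 1L, p = p, p_adj = NA_real_, d = d, n = n,
                 d_formula = d_formula, family_id = family_id,
                 degenerate = degen),
            class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf("paired t(%d) = %.3f, p = %.4g%s, d = %.3f (n = %d%s)\n",
              x$df, x$t, x$p,
              if (!is.na(x$p_adj)) sprintf(", p_adj = %.4g", x$p_adj) else "",
              x$d, x$n, if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment for one correction family
#'
#' Step-up adjusted p values (monotone, capped at 1) via
#' \code{stats::p.adjust(method = "BH")}. Families mirror the analysis
#' design: across lags per condition and synchrony measure for the paired
#' tests, across lags per measure for the mixed models, and across the six
#' pairwise contrasts within each mixed model.
#'
#' @param pvals numeric vector of raw p values in \code{[0, 1]}.
#' @param family_id optional label, attached as an attribute.
#' @return adjusted p values in input order.
#' @export
fdr_adjust <- function(pvals, family_id = NULL) {
  if (!length(pvals)) return(numeric())
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p values must be in [0, 1]")
  out <- stats::p.adjust(pvals, method = "BH")
  if (!is.null(family_id)) attr(out, "family_id") <- family_id
  out
}

#' Stack per-dyad synchrony profiles into a dyads x lags matrix
#'
#' @param profiles list of \code{dyad_synchrony} objects sharing a lag grid.
#' @return numeric matrix, one row per profile, columns named by lag.
#' @export
profiles_matrix <- function(profiles) {
  lags <- profiles[[1]]$lags
  m <- t(vapply(profiles, function(p) {
    stopifnot(identical(p$lags, lags))
    p$r
  }, numeric(length(lags))))
  colnames(m) <- sprintf("%+d", lags)
  rownames(m) <- vapply(profiles, function(p) p$dyad_id, character(1))
  m
}

#' Mirrored-lag comparisons (child-leads vs mother-leads)
#'
#' For each lag magnitude \code{k}, paired t test of the cohort's synchrony
#' at lag \code{-k} against lag \code{+k}; a positive mean difference means
#' stronger child-leads covariation. FDR is applied within the family of
#' mirrored pairs.
#'
#' @param mat dyads x lags matrix from [profiles_matrix()] (or a list of
#'   profiles, converted automatically).
#' @param family_id correction-family label.
#' @return data frame with one row per lag pair: \code{lag_abs}, \code{t},
#'   \code{df}, \code{p}, \code{p_adj}, \code{d}, \code{n}.
#' @export
compare_lag_signs <- function(mat, family_id = "lag-signs") {
  if (is.list(mat) && !is.matrix(mat)) mat <- profiles_matrix(mat)
  ks <- sort(unique(abs(as.integer(colnames2lags(mat)))))
  ks <- ks[ks > 0]
  tests <- lapply(ks, function(k) {
    paired_t(mat[, sprintf("%+d", -k)], mat[, sprintf("%+d", k)],
             family_id = family_id)
  })
  out <- data.frame(lag_abs = ks,
                    t = vapply(tests, `[[`, numeric(1), "t"),
                    df = vapply(tests, `[[`, integer(1), "df"),
                    p = vapply(tests, `[[`, numeric(1), "p"),
                    d = vapply(tests, `[[`, numeric(1), "d"),
                    n = vapply(tests, `[[`, integer(1), "n"))
  out$p_adj <- fdr_adjust(out$p, family_id)
  out[, c("lag_abs", "t", "df", "p", "p_adj", "d", "n")]
}

colnames2lags <- function(mat) as.integer(sub("^\\+", "", colnames(mat)))

#' Condition effect on synchrony: linear mixed model
#'
#' REML fit of \code{value ~ condition + (1 | dyad)} via \code{lme4} /
#' \code{lmerTest}, Satterthwaite-approximated F test of the condition
#' effect, marginal R-squared
#' \code{var_fixed / (var_fixed + var_random + var_residual)}, and the six
#' pairwise condition contrasts (estimated marginal means) with FDR over
#' the contrast family. Unbalanced data (dyads missing conditions) are
#' handled natively by REML; nothing is imputed. A singular random-effects
#' fit is flagged but the fixed-effects test is still returned.
#'
#' @param df data frame with columns \code{dyad_id}, \code{condition},
#'   \code{value}.
#' @return an object of class \code{condition_lmm}: list with \code{F},
#'   \code{df_num}, \code{df_den}, \code{p}, \code{p_adj} (NA until a
#'   family-level [fdr_adjust()]), \code{r_squared_marginal},
#'   \code{contrasts} data frame, \code{singular}, and the fitted model.
#' @export
condition_lmm <- function(df) {
  stopifnot(all(c("dyad_id", "condition", "value") %in% names(df)))
  df <- df[!is.na(df$value), , drop = FALSE]
  tab <- table(unique(df[, c("dyad_id", "condition")])$condition)
  if (sum(tab >= 3) < 2) stop("need >= 2 conditions with >= 3 dyads each")
  df$condition <- factor(df$condition)
  df$dyad_id <- factor(df$dyad_id)
  if (stats::var(df$value) == 0) {
    # constant response: no fixed-effect variance to test
    return(structure(list(F = 0, df_num = length(levels(df$condition)) - 1L,
                          df_den = NA_real_, p = 1, p_adj = NA_real_,
                          r_squared_marginal = 0,
                          contrasts = data.frame(), singular = TRUE,
                          model = NULL),
                     class = "condition_lmm"))
  }
  fit <- suppressMessages(
    lmerTest::lmer(value ~ condition + (1 | dyad_id), data = df, REML = TRUE))
  an <- stats::anova(fit)         # Satterthwaite by default for lmerTest
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_rand <- sum(vc$vcov[vc$grp != "Residual"])
  var_resid <- vc$vcov[vc$grp == "Residual"]
  var_fixed <- stats::var(as.numeric(lme4::getME(fit, "X") %*% lme4::fixef(fit)))
  r2 <- var_fixed / (var_fixed + var_rand + var_resid)
  emm <- emmeans::emmeans(fit, "condition")
  ctr <- as.data.frame(emmeans::contrast(emm, method = "pairwise", adjust = "none"))
  ctr$p_adj <- fdr_adjust(ctr$p.value, "lmm-contrasts")
  structure(list(F = an[1, "F value"], df_num = an[1, "NumDF"],
                 df_den = an[1, "DenDF"], p = an[1, "Pr(>F)"],
                 p_adj = NA_real_, r_squared_marginal = r2,
                 contrasts = ctr, singular = lme4::isSingular(fit),
                 model = fit),
            class = "condition_lmm")
}

#' @export
print.condition_lmm <- function(x, ...) {
  cat(sprintf("condition effect: F(%d, %.1f) = %.2f, p = %.4g, marginal R^2 = %.3f%s\n",
              x$df_num, x$df_den, x$F, x$p, x$r_squared_marginal,
              if (x$singular) " (singular random-effects fit)" else ""))
  print(x$contrasts[, c("contrast", "estimate", "p.value", "p_adj")])
  invisible(x)
}

#' Across-dyad correlation table
#'
#' Bivariate Pearson correlations (with two-sided p) between per-dyad
#' summary variables -- e.g. lag-0 IBI/RSA synchrony and affect fractions --
#' using pairwise-complete deletion. Cells with fewer than 4 complete pairs
#' or zero variance are left missing.
#'
#' @param df data frame of numeric per-dyad variables (one row per dyad).
#' @return list of matrices \code{r}, \code{p}, \code{n}.
#' @export
across_dyad_correlations <- function(df) {
  df <- as.data.frame(df)
  v <- names(df)
  k <- length(v)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(v, v))
  n <- matrix(0L, k, k, dimnames = list(v, v))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      ok <- !is.na(df[[i]]) & !is.na(df[[j]])
      n[i, j] <- sum(ok)
      if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
      if (n[i, j] >= 4 && stats::sd(df[[i]][ok]) > 0 && stats::sd(df[[j]][ok]) > 0) {
        ct <- stats::cor.test(df[[i]][ok], df[[j]][ok])
        r[i, j] <- unname(ct$estimate)
        p[i, j] <- ct$p.value
      }
    }
  }
  list(r = r, p = p, n = n)
}
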