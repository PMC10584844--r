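test_that("the paired t test matches hand computation and handles degeneracy", {
  x <- c(0.2, 0.3, 0.4); y <- c(0.0, 0.1, 0.1)
  tt <- paired_t(x, y)
  expect_equal(tt$t, 7, tolerance = 1e-10)
  expect_equal(tt$df, 2L)
  expect_equal(tt$d, mean(x - y) / sd(x - y))

  # identical vectors: degenerate path with t = 0, p = 1
  tt <- paired_t(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_true(tt$degenerate)
  expect_equal(tt$t, 0)
  expect_equal(tt$p, 1)

  # random pairs against the textbook formula
  set.seed(51)
  for (i in 1:10) {
    x <- rnorm(15); y <- rnorm(15)
    tt <- paired_t(x, y)
    d <- x - y
    expect_equal(tt$t, mean(d) / (sd(d) / sqrt(15)), tolerance = 1e-10)
    expect_equal(tt$p, 2 * pt(-abs(tt$t), 14), tolerance = 1e-10)
  }

  # listwise deletion of incomplete pairs
  tt <- paired_t(c(1, 2, NA, 4, 5), c(0, NA, 2, 3, 4))
  expect_equal(tt$n, 3L)
})

test_that("FDR adjustment equals the step-up definition", {
  expect_equal(fdr_adjust(c(0.005, 0.02, 0.03)), c(0.015, 0.03, 0.03))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(numeric()), numeric())
  expect_error(fdr_adjust(c(0.5, 1.2)), "must be in")

  set.seed(52)
  for (i in 1:100) {
    p <- runif(sample(1:20, 1))
    expect_equal(fdr_adjust(p), bh_oracle(p))
  }

  # monotone transform of the raw ranks, capped at 1
  p <- sort(runif(10))
  adj <- fdr_adjust(p)
  expect_true(all(diff(adj) >= -1e-12))
  expect_true(all(adj >= p & adj <= 1))
})

test_that("mirrored-lag comparisons flag asymmetric profiles only", {
  lags <- -3:3
  mk <- function(rows) {
    m <- do.call(rbind, rows)
    colnames(m) <- sprintf("%+d", lags)
    m
  }
  # identical profiles: all t = 0
  set.seed(53)
  base <- runif(7, -0.1, 0.3)
  m <- mk(replicate(10, base, simplify = FALSE))
  out <- compare_lag_signs(m)
  expect_equal(out$t, rep(0, 3))

  # planted child-leads asymmetry at |lag| = 2
  rows <- replicate(20, {
    r <- rnorm(7, 0, 0.05)
    r[lags == -2] <- r[lags == -2] + 0.3
    r
  }, simplify = FALSE)
  out <- compare_lag_signs(mk(rows))
  expect_lt(out$p_adj[out$lag_abs == 2], 0.05)
  expect_gt(out$t[out$lag_abs == 2], 0)
  expect_gt(min(out$p[out$lag_abs != 2]), 0.05)
})

test_that("the condition mixed model matches the paired t on balanced data", {
  set.seed(54)
  n <- 20
  intercepts <- rnorm(n, sd = 0.05)
  df <- data.frame(
    dyad_id = rep(sprintf("d%02d", 1:n), 2),
    condition = rep(c("Rest", "La1"), each = n),
    value = c(intercepts + rnorm(n, 0, 0.04),
              intercepts + 0.08 + rnorm(n, 0, 0.04)))
  fit <- condition_lmm(df)
  tt <- paired_t(df$value[df$condition == "La1"], df$value[df$condition == "Rest"])
  expect_equal(fit$F, tt$t^2, tolerance = 0.01)
  expect_equal(fit$df_num, 1L)
  expect_gt(fit$r_squared_marginal, 0)
  expect_equal(nrow(fit$contrasts), 1L)

  # four conditions: six pairwise contrasts
  df4 <- data.frame(
    dyad_id = rep(sprintf("d%02d", 1:n), 4),
    condition = rep(conditions(), each = n),
    value = rnorm(4 * n))
  expect_equal(nrow(condition_lmm(df4)$contrasts), 6L)

  # constant response: zero fixed-effect variance, zero marginal R^2
  dfc <- df
  dfc$value <- 1
  fitc <- condition_lmm(dfc)
  expect_equal(fitc$r_squared_marginal, 0)
})

test_that("the condition F test holds its nominal type-I rate", {
  set.seed(55)
  reps <- 300
  n <- 12
  pvals <- replicate(reps, {
    df <- data.frame(
      dyad_id = rep(sprintf("d%02d", 1:n), 4),
      condition = rep(conditions(), each = n),
      value = rep(rnorm(n, sd = 0.05), 4) + rnorm(4 * n, sd = 0.05))
    fit <- suppressMessages(condition_lmm(df))
    fit$p
  })
  rate <- mean(pvals < 0.05)
  expect_lt(rate, 0.05 + 2 * sqrt(0.05 * 0.95 / reps) + 0.005)
})

test_that("across-dyad correlations use pairwise-complete Pearson", {
  set.seed(56)
  df <- data.frame(a = rnorm(8), b = rnorm(8), c = rnorm(8))
  df$b[2] <- NA
  out <- across_dyad_correlations(df)
  expect_equal(diag(out$r), c(a = 1, b = 1, c = 1))
  ok <- !is.na(df$b)
  expect_equal(out$r["a", "b"], pearson_oracle(df$a[ok], df$b[ok]),
               tolerance = 1e-10)
  expect_equal(out$n["a", "b"], 7L)
  ct <- cor.test(df$a, df$c)
  expect_equal(out$p["a", "c"], ct$p.value, tolerance = 1e-10)

  # zero-variance variable: missing cells, not NaN crashes
  df$z <- 1
  out <- across_dyad_correlations(df)
  expect_true(is.na(out$r["a", "z"]))
})
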