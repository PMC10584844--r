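test_that("polynomial detrending matches least squares exactly", {
  t <- 0:99
  y <- 3 + 2 * t + t^2
  dt <- detrend_poly(y, 2)
  expect_lt(max(abs(dt$residuals)), 1e-8)

  set.seed(10)
  y <- rnorm(200)
  dt <- detrend_poly(y, 2)
  X <- outer(0:199, 0:2, `^`)
  expect_equal(dt$residuals, ols_residuals_oracle(X, y), tolerance = 1e-10,
               ignore_attr = TRUE)

  # a sinusoid barely projects onto the quadratic basis
  y <- sin(2 * pi * (0:599) / 25)
  dt <- detrend_poly(y, 2)
  expect_gt(var(dt$residuals) / var(y), 0.95)

  expect_error(detrend_poly(c(1, 2, 3), 2), "too short")
})

test_that("ARIMA pre-whitening recovers parameters and whitens autocorrelation", {
  # constant input: degenerate, all-zero residuals
  pw <- arima_prewhiten(rep(5, 100))
  expect_true(pw$report$degenerate)
  expect_true(all(pw$values == 0))
  expect_length(pw$values, 99L)

  # parameter recovery on self-simulated ARIMA(1,1,1)
  set.seed(11)
  x <- cumsum(arima.sim(list(ar = 0.5, ma = 0.3), 5000))
  pw <- arima_prewhiten(x)
  expect_equal(pw$report$ar, 0.5, tolerance = 0.05 / 0.5)
  expect_equal(pw$report$ma, 0.3, tolerance = 0.05 / 0.3)
  expect_true(pw$report$converged)
  expect_length(pw$values, 5000L - 1L)

  # AR(1) input: residuals are white at lag 1
  set.seed(12)
  x <- arima.sim(list(ar = 0.7), 2000)
  pw <- arima_prewhiten(x)
  rho1 <- cor(pw$values[-1], pw$values[-length(pw$values)])
  expect_lt(abs(rho1), 2 / sqrt(length(pw$values)))

  expect_error(arima_prewhiten(rnorm(20)), "too short")
})

test_that("lagged cross-correlation obeys its sign convention and the oracle", {
  set.seed(13)
  x <- rnorm(100)
  prof <- cross_correlation_profile(x, x, 3)
  expect_equal(prof$r[prof$lags == 0], 1)
  expect_equal(prof$n_overlap, 100L - abs(-3:3))

  # child[t] = mother[t-2]: mother leads by 2 s, so r(+2) = 1
  m <- rnorm(120)
  ch <- c(0, 0, m[1:118])
  prof <- cross_correlation_profile(m, ch, 3)
  expect_equal(prof$r[prof$lags == 2], 1, tolerance = 1e-12)
  expect_lt(prof$r[prof$lags == 0], 1)

  # degenerate overlap: zero variance yields an invalid (NA) lag, not a crash
  z <- c(rep(1, 50), rnorm(10))
  prof <- cross_correlation_profile(z, rev(z), 3)
  expect_true(all(is.finite(prof$r) | is.na(prof$r)))
})

test_that("short-series cross-correlation matches the oracle at n >= 30", {
  set.seed(14)
  for (i in 1:10) {
    a <- rnorm(40); b <- rnorm(40)
    prof <- cross_correlation_profile(a, b, 3)
    expect_equal(prof$r, xcorr_oracle(a, b, 3), tolerance = 1e-12)
  }
})

test_that("swapping partners mirrors the profile", {
  set.seed(15)
  for (i in 1:5) {
    a <- rnorm(60); b <- rnorm(60)
    p1 <- cross_correlation_profile(a, b, 3)
    p2 <- cross_correlation_profile(b, a, 3)
    expect_equal(p2$r, rev(p1$r), tolerance = 1e-12)
    expect_true(all(abs(p1$r) <= 1))
  }
})

test_that("pre-whitening controls the false-positive rate that raw series inflate", {
  set.seed(16)
  n <- 300; reps <- 150
  raw_hit <- white_hit <- logical(reps)
  crit <- qnorm(0.975) / sqrt(n - 1)
  for (i in seq_len(reps)) {
    a <- as.numeric(arima.sim(list(ar = 0.95), n))
    b <- as.numeric(arima.sim(list(ar = 0.95), n))
    raw_hit[i] <- abs(cor(a, b)) > crit
    wa <- arima_prewhiten(a)$values
    wb <- arima_prewhiten(b)$values
    white_hit[i] <- abs(cor(wa, wb)) > crit
  }
  expect_gt(mean(raw_hit), 0.3)               # raw autocorrelation inflates badly
  expect_lt(mean(white_hit), 0.05 + 2 * sqrt(0.05 * 0.95 / reps))
  expect_lt(mean(white_hit), mean(raw_hit))
})

# frozen output of the composed pipeline on one fixed seeded dyad; guards
# against silent changes anywhere in resample -> epoch -> detrend -> ARIMA ->
# cross-correlation
golden_profile_r <- c(0.0319929856, 0.4756336497, 0.1064179622, -0.0632778632,
                      0.1478762641, 0.0018311695, -0.0888026042)

test_that("the full per-dyad pipeline reproduces a frozen golden profile", {
  cfg <- sim_config(n_dyads = 1, duration_s = 120, seed = 20240101)
  coh <- simulate_cohort(cfg)
  fit <- compute_synchrony(coh$dyads$d001$La1, "ibi",
                           dyad_id = "d001", condition = "La1")
  expect_s3_class(fit, "dyad_synchrony")
  expect_equal(fit$lags, -3:3)
  expect_true(all(abs(fit$r) <= 1))
  # frozen snapshot guarding the whole composition (detrend -> ARIMA -> xcorr)
  expect_equal(fit$r, golden_profile_r, tolerance = 1e-6)
})
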