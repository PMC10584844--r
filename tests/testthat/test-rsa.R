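test_that("spline interpolation reproduces constants, lines and slow sinusoids", {
  rp <- constant_rpeaks(800, 60)
  x4 <- interpolate_ibi(rp, 4)
  expect_equal(x4$values[x4$valid], rep(800, sum(x4$valid)), tolerance = 1e-9)

  # linearly ramping IBI: spline is exact on linear data
  t <- 0; times <- 0
  repeat {
    ibi <- 0.7 + 0.0005 * t
    t <- t + ibi
    if (t > 60) break
    times <- c(times, t)
  }
  rp <- rpeaks(times, duration_s = 60)
  x4 <- interpolate_ibi(rp, 4)
  knots_x <- rp$times_s[-1]
  knots_y <- diff(rp$times_s) * 1000
  line <- stats::lm(knots_y ~ knots_x)
  pred <- predict(line, data.frame(knots_x = x4$times_s[x4$valid]))
  expect_equal(x4$values[x4$valid], unname(pred), tolerance = 1e-6)

  # sinusoidal heart-period target recovered within 5 ms; the interval
  # closing at beat t[i+1] carries m(t[i]), so the reconstructed series is
  # the target delayed by one beat (~0.8 s)
  m <- function(t) 800 + 40 * sin(2 * pi * 0.25 * t)
  rp <- rr_target_to_rpeaks(m, 120)
  x4 <- interpolate_ibi(rp, 4)
  ok <- x4$valid & x4$times_s > 2 & x4$times_s < 118
  expect_lt(max(abs(x4$values[ok] - m(x4$times_s[ok] - 0.8))), 5)

  expect_error(interpolate_ibi(rpeaks(c(0, 1, 2)), 4), "insufficient")
})

test_that("band power rejects DC and out-of-band energy and scales quadratically", {
  fs <- 4
  mk <- function(f, A, n = 1201) {
    tt <- (0:(n - 1)) / fs
    list(values = 800 + A * sin(2 * pi * f * tt), valid = rep(TRUE, n),
         times_s = tt, rate = fs)
  }
  # constant series: no in-band energy after demeaning
  const <- list(values = rep(800, 1201), valid = rep(TRUE, 1201),
                times_s = (0:1200) / 4, rate = 4)
  bp <- sliding_band_power(const)
  expect_lt(max(bp$power, na.rm = TRUE), 1e-10 * 800^2 * 128)

  bp1 <- sliding_band_power(mk(0.25, 40))
  bp2 <- sliding_band_power(mk(0.25, 80))
  interior <- 30:270
  ratio <- bp2$power[interior] / bp1$power[interior]
  expect_equal(mean(ratio), 4, tolerance = 0.02)

  bp_out <- sliding_band_power(mk(0.05, 40))
  expect_lt(mean(bp_out$power[interior]) / mean(bp1$power[interior]), 0.05)
})

test_that("RSA series is the log of band power with the documented valid span", {
  bp <- list(power = c(NA, 1, exp(1), exp(2), NA),
             valid = c(FALSE, TRUE, TRUE, TRUE, FALSE),
             center_s = 0:4)
  rs <- rsa_series(bp)
  expect_equal(rs$values[2:4], c(0, 1, 2), tolerance = 1e-9)
  expect_equal(rs$valid, bp$valid)
  expect_error(rsa_series(list(power = -1, valid = TRUE)), "nonnegative")

  # 300-s recording with defaults: exactly 270 valid seconds, the first and
  # final 15 s carrying none
  rp <- sinus_rpeaks(300)
  rs <- rsa_epoch_series(rp)
  expect_equal(sum(rs$valid), 270L)
  expect_false(any(rs$valid[1:15]))
  expect_false(any(rs$valid[286:300]))
  expect_true(all(rs$valid[16:285]))
})

test_that("per-second RSA is stable, monotone in depth and consistent in the mean", {
  rp <- sinus_rpeaks(300, depth_ms = 40)
  rs <- rsa_epoch_series(rp)
  interior <- 31:270
  v <- exp(rs$values[interior])      # back to power scale for the CV
  expect_lt(sd(v) / mean(v), 0.10)

  # monotone in modulation depth
  depths <- c(10, 20, 30, 40, 50)
  med <- sapply(depths, function(d) {
    median(rsa_epoch_series(sinus_rpeaks(300, depth_ms = d))$values,
           na.rm = TRUE)
  })
  expect_true(all(diff(med) > 0))

  # mean per-second band power agrees with one full-series multitaper
  # estimate after normalising both to per-sample scale
  x4 <- interpolate_ibi(sinus_rpeaks(300, depth_ms = 40), 4)
  bp <- sliding_band_power(x4)
  n_full <- sum(x4$valid)
  tap <- dpss_tapers(n_full, 2.5, 3)
  seg <- x4$values[x4$valid]
  seg <- seg - mean(seg)
  fr <- (0:(n_full - 1)) * 4 / n_full
  sel <- fr >= 0.12 & fr <= 0.40
  acc <- 0
  for (j in 1:3) acc <- acc + Mod(stats::fft(seg * tap[, j]))^2
  full <- sum(acc[sel]) / 3 / n_full
  expect_equal(mean(bp$power, na.rm = TRUE) / 128, full, tolerance = 0.05)
})

test_that("the Slepian taper bank is orthonormal and band-concentrated", {
  V <- dpss_tapers(128, 2.5, 3)
  expect_equal(t(V) %*% V, diag(3), tolerance = 1e-8)
  # concentration: most energy within +/- nw/n cycles/sample
  for (j in 1:3) {
    spec <- Mod(stats::fft(c(V[, j], rep(0, 128 * 7))))^2
    fr <- (0:(length(spec) - 1)) / length(spec)
    inb <- fr <= 2.5 / 128 | fr >= 1 - 2.5 / 128
    expect_gt(sum(spec[inb]) / sum(spec), 0.95)
  }
})
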