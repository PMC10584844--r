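test_that("affect simulation hits its stationary rate and imitation limit", {
  cfg0 <- sim_config(n_dyads = 1, duration_s = 100, affect_rate = 0)
  set.seed(1)
  aff <- simulate_affect(cfg0)
  expect_true(all(aff$mother == 0L) && all(aff$child == 0L))

  cfg <- sim_config(n_dyads = 1, duration_s = 10000, affect_rate = 0.1,
                    affect_mean_bout_s = 4)
  set.seed(2)
  aff <- simulate_affect(cfg)
  expect_equal(mean(aff$child), 0.1, tolerance = 0.01 / 0.1)
  # follower's marginal rate stays near the target too
  expect_equal(mean(aff$mother), 0.1, tolerance = 0.25)

  # deterministic imitation limit: mother = child shifted by +2 s at lag -2
  cfg1 <- sim_config(n_dyads = 1, duration_s = 200, imitation_prob = 1,
                     coupling_lag_s = -2)
  set.seed(3)
  aff <- simulate_affect(cfg1)
  n <- 200
  expect_equal(aff$mother[3:n], aff$child[1:(n - 2)])
  expect_equal(aff$mother[1:2], c(0L, 0L))

  # infeasible (rate, bout) combination
  cfgbad <- sim_config(n_dyads = 1, affect_rate = 0.9, affect_mean_bout_s = 1)
  expect_error(simulate_affect(cfgbad), "infeasible")
})

test_that("heart-period target composes its components as specified", {
  cfg <- sim_config(n_dyads = 1, duration_s = 50, rsa_mod_depth_ms = 0,
                    noise_sd_ms = 0, coupling_gain = 0)
  m <- simulate_rr_target(cfg, "child")
  expect_equal(m(c(0, 13.7, 42)), rep(700, 3))

  # respiration-band amplitude doubles during affect when affect_rsa_gain = 1
  cfg2 <- sim_config(n_dyads = 1, duration_s = 50, rsa_mod_depth_ms = 30,
                     affect_rsa_gain = 1, affect_rr_effect_ms = 0,
                     noise_sd_ms = 0, coupling_gain = 0)
  aff_on <- rep(1L, 50)
  m_on <- simulate_rr_target(cfg2, "child", affect = aff_on)
  m_off <- simulate_rr_target(cfg2, "child", affect = integer(50))
  tt <- seq(0, 49, by = 0.05)
  expect_equal(max(m_on(tt)) - 700, 2 * (max(m_off(tt)) - 700), tolerance = 1e-3)

  # nonphysiological target rejected
  cfg3 <- sim_config(n_dyads = 1, duration_s = 10, noise_sd_ms = 0,
                     mean_rr_child_ms = 210, rsa_mod_depth_ms = 30)
  expect_error(simulate_rr_target(cfg3, "child"), "nonphysiological")
})

test_that("beat generation follows the forward recursion exactly", {
  rp <- rr_target_to_rpeaks(function(t) rep(800, length(t)), 4)
  expect_equal(rp$times_s, c(0, 0.8, 1.6, 2.4, 3.2, 4.0))

  rp <- rr_target_to_rpeaks(function(t) rep(1000, length(t)), 300)
  expect_equal(rp$n, 301L)

  # sinusoidal target: interval i equals m evaluated at peak i (recursion oracle)
  m <- function(t) 800 + 40 * sin(2 * pi * 0.25 * t)
  rp <- rr_target_to_rpeaks(m, 60)
  expect_equal(diff(rp$times_s) * 1000, m(rp$times_s[-rp$n]), tolerance = 1e-12)
})

test_that("generated cohorts match their configuration and are reproducible", {
  cfg <- sim_config(n_dyads = 2, duration_s = 120, seed = 5)
  coh <- simulate_cohort(cfg)
  expect_length(coh$dyads, 2L)
  expect_named(coh$dyads[[1]], conditions())
  expect_equal(nrow(coh$ground_truth), 8L)
  # coupling only in the interactive games
  expect_equal(coh$ground_truth$coupling_gain[coh$ground_truth$condition == "Rest"],
               c(0, 0))
  expect_true(all(coh$ground_truth$coupling_gain[
    coh$ground_truth$condition == "La1"] == cfg$coupling_gain))
  # affect coded only in La1/La2
  expect_false(any(coh$dyads$d001$Rest$affect$child == 1L))

  # empirical mean RR within 1% of configured at 300 s
  cfg3 <- sim_config(n_dyads = 1, duration_s = 300, seed = 8)
  coh3 <- simulate_cohort(cfg3)
  expect_equal(mean(ibi_ms(coh3$dyads$d001$Rest$child)), cfg3$mean_rr_child_ms,
               tolerance = 0.01)
  expect_equal(mean(ibi_ms(coh3$dyads$d001$Rest$mother)), cfg3$mean_rr_adult_ms,
               tolerance = 0.01)

  # seeded determinism
  coh_b <- simulate_cohort(cfg)
  expect_identical(coh_b$dyads$d002$La2$mother$times_s,
                   coh$dyads$d002$La2$mother$times_s)
})

test_that("the injected coupling lag dominates the latent cross-correlation", {
  # noiseless check on the simulator's own 1-s means: brute-force argmax
  cfg <- sim_config(n_dyads = 1, duration_s = 300, noise_sd_ms = 0,
                    rsa_mod_depth_ms = 0, affect_rate = 0, coupling_gain = 50,
                    coupling_lag_s = -2)
  set.seed(21)
  latent <- dyadsync:::ou_latent(-10, 310, cfg$latent_timescale_s)
  m_c <- simulate_rr_target(cfg, "child", latent = latent)
  m_m <- simulate_rr_target(cfg, "mother", latent = latent)
  sec_mean <- function(m) {
    tt <- seq(0.05, 300, by = 0.1)
    colMeans(matrix(m(tt), nrow = 10))
  }
  r <- xcorr_oracle(sec_mean(m_m), sec_mean(m_c), 3)
  expect_equal((-3:3)[which.max(r)], -2L)
})
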