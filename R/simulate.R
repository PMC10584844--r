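#' Simulation configuration for synthetic coupled dyads
#'
#' Parameters of the coupled-dyad generator. Each partner's instantaneous
#' heart period is a baseline plus (i) a shared, lag-shifted
#' Ornstein-Uhlenbeck latent process scaled by \code{coupling_gain}, (ii) a
#' respiration-band sinusoid whose amplitude is modulated by the partner's
#' binary positive-affect state, (iii) a heart-period shift during affect,
#' and (iv) white noise. Beats are generated from the heart-period function
#' by forward recursion. Affect is a two-state Markov chain for the leading
#' partner; the follower imitates episodes at a configurable probability and
#' time shift.
#'
#' Negative \code{coupling_lag_s} means the child's signals lead the
#' mother's (the convention used for synchrony lags throughout).
#'
#' @param n_dyads number of dyads.
#' @param duration_s recording length per condition, seconds.
#' @param mean_rr_adult_ms,mean_rr_child_ms baseline heart periods, ms.
#' @param resp_freq_hz length-2 numeric (adult, child) respiration
#'   frequencies, Hz; must lie in the analysis band.
#' @param rsa_mod_depth_ms amplitude of the respiration-band heart-period
#'   oscillation, ms.
#' @param coupling_gain scale (ms per latent SD) of the shared latent in both
#'   partners' heart periods; active only in interactive conditions.
#' @param coupling_lag_s signed integer lag, seconds; negative = child leads.
#' @param latent_timescale_s Ornstein-Uhlenbeck relaxation time, seconds.
#' @param affect_rate stationary probability of positive affect.
#' @param affect_mean_bout_s mean length of an affect episode, seconds.
#' @param affect_rr_effect_ms heart-period change while affect is on, ms
#'   (negative = heart rate speeds up).
#' @param affect_rsa_gain multiplicative change of the respiration-band
#'   amplitude while affect is on.
#' @param imitation_prob probability that the follower imitates a leader
#'   affect episode.
#' @param noise_sd_ms SD of per-second white heart-period noise, ms.
#' @param seed integer seed for [simulate_cohort()].
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(n_dyads = 10, duration_s = 300,
                       mean_rr_adult_ms = 850, mean_rr_child_ms = 700,
                       resp_freq_hz = c(0.25, 0.30),
                       rsa_mod_depth_ms = 35,
                       coupling_gain = 80, coupling_lag_s = -2L,
                       latent_timescale_s = 10,
                       affect_rate = 0.10, affect_mean_bout_s = 4,
                       affect_rr_effect_ms = -40, affect_rsa_gain = 0.5,
                       imitation_prob = 0.7,
                       noise_sd_ms = 10, seed = 1L) {
  cfg <- list(n_dyads = as.integer(n_dyads), duration_s = duration_s,
              mean_rr_adult_ms = mean_rr_adult_ms,
              mean_rr_child_ms = mean_rr_child_ms,
              resp_freq_hz = resp_freq_hz,
              rsa_mod_depth_ms = rsa_mod_depth_ms,
              coupling_gain = coupling_gain,
              coupling_lag_s = as.integer(coupling_lag_s),
              latent_timescale_s = latent_timescale_s,
              affect_rate = affect_rate,
              affect_mean_bout_s = affect_mean_bout_s,
              affect_rr_effect_ms = affect_rr_effect_ms,
              affect_rsa_gain = affect_rsa_gain,
              imitation_prob = imitation_prob,
              noise_sd_ms = noise_sd_ms, seed = as.integer(seed))
  stopifnot(cfg$duration_s >= 1, cfg$mean_rr_adult_ms > 0,
            cfg$mean_rr_child_ms > 0, all(cfg$resp_freq_hz > 0),
            cfg$latent_timescale_s > 0, cfg$affect_mean_bout_s >= 1,
            cfg$noise_sd_ms >= 0, abs(cfg$coupling_lag_s) <= 3)
  if (cfg$affect_rate < 0 || cfg$affect_rate >= 1) {
    stop("affect_rate must be in [0, 1)")
  }
  structure(cfg, class = "sim_config")
}

# Exact discretisation of a unit-variance Ornstein-Uhlenbeck process at 1 Hz,
# returned as a linearly interpolated function of continuous time.
ou_latent <- function(from_s, to_s, timescale_s) {
  tt <- seq(floor(from_s), ceiling(to_s), by = 1)
  a <- exp(-1 / timescale_s)
  n <- length(tt)
  x <- numeric(n)
  x[1] <- stats::rnorm(1)
  innov <- stats::rnorm(n - 1, sd = sqrt(1 - a^2))
  for (i in seq_len(n - 1)) x[i + 1] <- a * x[i] + innov[i]
  stats::approxfun(tt, x, rule = 2)
}

#' Simulate binary positive-affect series for one dyad
#'
#' The leading partner's affect is a two-state Markov chain at 1 Hz with
#' stationary on-probability \code{affect_rate} and mean on-run length
#' \code{affect_mean_bout_s}. The follower imitates each leader episode with
#' probability \code{imitation_prob}, shifted by \code{|coupling_lag_s|}
#' seconds, and adds an independent chain at rate
#' \code{affect_rate * (1 - imitation_prob)} so its marginal rate stays near
#' \code{affect_rate}. With \code{coupling_lag_s <= 0} the child leads.
#'
#' Uses the current RNG stream.
#'
#' @param cfg a [sim_config()].
#' @return list with binary integer vectors \code{mother} and \code{child}
#'   of length \code{duration_s}.
#' @export
simulate_affect <- function(cfg) {
  n <- as.integer(cfg$duration_s)
  rate <- cfg$affect_rate
  if (rate == 0) {
    z <- integer(n)
    return(list(mother = z, child = z))
  }
  p_off <- 1 / cfg$affect_mean_bout_s              # P(on -> off)
  p_on <- p_off * rate / (1 - rate)                # P(off -> on)
  if (p_on > 1) {
    stop("infeasible (affect_rate, affect_mean_bout_s) combination")
  }
  lead <- markov_chain(n, p_on, p_off, rate)
  L <- cfg$coupling_lag_s
  follow <- imitate_episodes(lead, shift = abs(L), prob = cfg$imitation_prob)
  if (cfg$imitation_prob < 1) {
    topup_rate <- rate * (1 - cfg$imitation_prob)
    own <- markov_chain(n, p_off * topup_rate / (1 - topup_rate), p_off, topup_rate)
    follow <- as.integer(follow | own)
  }
  if (L <= 0) list(mother = follow, child = lead)
  else list(mother = lead, child = follow)
}

markov_chain <- function(n, p_on, p_off, stationary) {
  x <- integer(n)
  u <- stats::runif(n)
  x[1] <- as.integer(u[1] < stationary)
  for (i in 2:n) {
    x[i] <- if (x[i - 1] == 1L) as.integer(u[i] >= p_off) else as.integer(u[i] < p_on)
  }
  x
}

# Copy each on-run of `lead`, delayed by `shift` seconds, with probability
# `prob`; runs shifted past the end are truncated.
imitate_episodes <- function(lead, shift, prob) {
  n <- length(lead)
  out <- integer(n)
  r <- rle(lead)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep_on <- which(r$values == 1L)
  for (j in keep_on) {
    if (stats::runif(1) <= prob) {
      i0 <- starts[j] + shift
      i1 <- ends[j] + shift
      if (i0 <= n) out[i0:min(i1, n)] <- 1L
    }
  }
  out
}

#' Build the instantaneous heart-period function for one participant
#'
#' \code{m(t) = mean_rr + coupling_gain * latent(t + lag_role) +
#' rsa_mod_depth * (1 + affect_rsa_gain * affect(t)) * sin(2 pi f_resp t) +
#' affect_rr_effect * affect(t) + noise(t)} in milliseconds. The latent shift
#' \code{lag_role} is \code{coupling_lag_s} for the mother and 0 for the
#' child, so a negative lag delays the mother's copy of the shared latent
#' (child leads). Noise is white at 1 Hz and held constant within each
#' second. Uses the current RNG stream (for the noise).
#'
#' @param cfg a [sim_config()].
#' @param role \code{"mother"} or \code{"child"}.
#' @param affect binary per-second vector for this participant (recycled to
#'   zero outside its range); use \code{integer(duration)} for none.
#' @param latent function of continuous time (shared within the dyad), or
#'   \code{NULL} for no coupling.
#' @param coupling_gain gain applied to the latent, ms; 0 disables coupling.
#' @return function \code{m(t)} vectorised over \code{t}, returning ms.
#' @export
simulate_rr_target <- function(cfg, role = c("child", "mother"), affect = NULL,
                               latent = NULL, coupling_gain = cfg$coupling_gain) {
  role <- match.arg(role)
  mean_rr <- if (role == "mother") cfg$mean_rr_adult_ms else cfg$mean_rr_child_ms
  f_resp <- if (role == "mother") cfg$resp_freq_hz[1] else cfg$resp_freq_hz[2]
  lag_role <- if (role == "mother") cfg$coupling_lag_s else 0L
  n_sec <- as.integer(ceiling(cfg$duration_s))
  if (is.null(affect)) affect <- integer(n_sec)
  # participants breathe at their own phase; without this every same-role
  # pair in a cohort would share one phase-locked oscillator
  phase <- stats::runif(1, 0, 2 * pi)
  noise <- if (cfg$noise_sd_ms > 0) stats::rnorm(n_sec, sd = cfg$noise_sd_ms) else numeric(n_sec)
  aff_at <- function(t) {
    i <- floor(t) + 1
    ok <- i >= 1 & i <= length(affect)
    a <- numeric(length(t)); a[ok] <- affect[i[ok]]
    a
  }
  noise_at <- function(t) {
    i <- pmin(pmax(floor(t) + 1, 1), n_sec)
    noise[i]
  }
  m <- function(t) {
    a <- aff_at(t)
    v <- mean_rr +
      cfg$rsa_mod_depth_ms * (1 + cfg$affect_rsa_gain * a) * sin(2 * pi * f_resp * t + phase) +
      cfg$affect_rr_effect_ms * a + noise_at(t)
    if (!is.null(latent) && coupling_gain != 0) {
      v <- v + coupling_gain * latent(t + lag_role)
    }
    v
  }
  probe <- m(seq(0, cfg$duration_s, by = 0.1))
  if (any(probe <= 200)) {
    stop("nonphysiological heart-period target: m(t) <= 200 ms")
  }
  m
}

#' Generate R-peaks from a heart-period function
#'
#' Forward recursion \code{t[i+1] = t[i] + m(t[i]) / 1000} starting at
#' \code{t = 0}, stopping at \code{duration_s}; an integral-pulse-style beat
#' generator where each interbeat interval equals the instantaneous heart
#' period at the preceding beat.
#'
#' @param m heart-period function of time, ms (must exceed 200 ms).
#' @param duration_s recording duration, seconds.
#' @return an [rpeaks()] series.
#' @export
rr_target_to_rpeaks <- function(m, duration_s) {
  t <- numeric(ceiling(duration_s / 0.2) + 2L)
  t[1] <- 0
  i <- 1L
  repeat {
    dt <- m(t[i]) / 1000
    if (dt <= 0.2) stop("nonphysiological heart-period target: m(t) <= 200 ms")
    nxt <- t[i] + dt
    if (nxt > duration_s + 1e-9) break
    i <- i + 1L
    t[i] <- nxt
  }
  rpeaks(t[seq_len(i)], duration_s = duration_s)
}

#' Simulate a cohort of mother-child dyads with ground truth
#'
#' For every dyad and every condition (\code{Rest}, \code{Single},
#' \code{La1}, \code{La2}) a pair of R-peak series is generated; the shared
#' latent coupling and affect imitation are active only in the interactive
#' games (La1, La2), and affect is coded (non-empty) only there, mirroring
#' the study design. Each dyad draws from its own RNG substream derived from
#' \code{cfg$seed}, so cohorts are reproducible and dyads independent.
#'
#' @param cfg a [sim_config()].
#' @return an object of class \code{dyad_cohort}: list with \code{dyads}
#'   (per dyad, per condition: \code{mother}/\code{child} [rpeaks()] series
#'   and \code{affect} list), \code{ground_truth} data frame and
#'   \code{config}.
#' @export
simulate_cohort <- function(cfg) {
  set.seed(cfg$seed)
  dyad_seeds <- sample.int(.Machine$integer.max - 1L, cfg$n_dyads)
  ids <- sprintf("d%03d", seq_len(cfg$n_dyads))
  dyads <- vector("list", cfg$n_dyads)
  names(dyads) <- ids
  gt <- list()
  for (d in seq_len(cfg$n_dyads)) {
    set.seed(dyad_seeds[d])
    conds <- list()
    for (cond in conditions()) {
      interactive <- cond %in% c("La1", "La2")
      gain <- if (interactive) cfg$coupling_gain else 0
      latent <- if (gain != 0) {
        ou_latent(-abs(cfg$coupling_lag_s) - 5, cfg$duration_s + abs(cfg$coupling_lag_s) + 5,
                  cfg$latent_timescale_s)
      } else NULL
      affect <- if (interactive) simulate_affect(cfg)
                else list(mother = integer(cfg$duration_s), child = integer(cfg$duration_s))
      m_child <- simulate_rr_target(cfg, "child", affect$child, latent, gain)
      m_mother <- simulate_rr_target(cfg, "mother", affect$mother, latent, gain)
      conds[[cond]] <- list(
        mother = rr_target_to_rpeaks(m_mother, cfg$duration_s),
        child = rr_target_to_rpeaks(m_child, cfg$duration_s),
        affect = affect,
        affect_coded = interactive
      )
      gt[[length(gt) + 1L]] <- data.frame(
        dyad_id = ids[d], condition = cond,
        coupling_gain = gain,
        coupling_lag_s = if (gain != 0) cfg$coupling_lag_s else NA_integer_,
        seed = dyad_seeds[d]
      )
    }
    dyads[[d]] <- conds
  }
  structure(list(dyads = dyads, ground_truth = do.call(rbind, gt), config = cfg),
            class = "dyad_cohort")
}

#' @export
print.dyad_cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d dyads x %d conditions, %.0f s each\n",
              length(x$dyads), length(conditions()), x$config$duration_s))
  cat(sprintf("  coupling gain %.1f ms at lag %+d s (La1/La2 only), seed %d\n",
              x$config$coupling_gain, x$config$coupling_lag_s, x$config$seed))
  invisible(x)
}

#' Write a simulated cohort to disk in the pipeline's CSV formats
#'
#' Writes per-participant R-peak CSVs, affect annotation CSVs for the
#' interactive conditions, a cohort manifest readable by [read_manifest()],
#' and the ground truth as \code{ground_truth.csv}.
#'
#' @param cohort a \code{dyad_cohort}.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (id in names(cohort$dyads)) {
    for (cond in names(cohort$dyads[[id]])) {
      rec <- cohort$dyads[[id]][[cond]]
      for (role in c("mother", "child")) {
        rp <- sprintf("%s_%s_%s_rpeaks.csv", id, role, cond)
        write_rpeaks(rec[[role]], file.path(dir, rp))
        ap <- NA_character_
        if (isTRUE(rec$affect_coded)) {
          ap <- sprintf("%s_%s_%s_affect.csv", id, role, cond)
          write_affect_intervals(rec$affect[[role]], file.path(dir, ap))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          dyad_id = id, role = role, condition = cond,
          rpeak_path = rp, affect_path = ifelse(is.na(ap), "", ap))
      }
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(cohort$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(file.path(dir, "manifest.csv"))
}

# Binary per-second series -> "positive" annotation intervals.
write_affect_intervals <- function(series, path) {
  r <- rle(as.integer(series))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  on <- r$values == 1L
  df <- data.frame(code = rep("positive", sum(on)),
                   onset_s = starts[on], offset_s = ends[on])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
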