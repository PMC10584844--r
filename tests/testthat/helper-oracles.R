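# Independent oracles used across tests. These deliberately avoid the code
# paths they check: Pearson correlation from raw sums, BH step-up from its
# definition, least squares from the normal equations.

pearson_oracle <- function(a, b) {
  n <- length(a)
  sa <- sum(a); sb <- sum(b)
  num <- n * sum(a * b) - sa * sb
  den <- sqrt(n * sum(a^2) - sa^2) * sqrt(n * sum(b^2) - sb^2)
  num / den
}

# brute-force per-lag cross-correlation with per-lag re-centering
xcorr_oracle <- function(m, ch, max_lag) {
  n <- length(m)
  sapply(-max_lag:max_lag, function(k) {
    t <- seq(max(1, 1 - k), min(n, n - k))
    pearson_oracle(m[t], ch[t + k])
  })
}

# Benjamini-Hochberg step-up from the definition
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  if (n > 1) for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

ols_residuals_oracle <- function(X, y) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  as.numeric(y - X %*% beta)
}

# evenly spaced beats at a constant interbeat interval (ms)
constant_rpeaks <- function(ibi_ms, duration_s) {
  n <- floor(duration_s / (ibi_ms / 1000) + 1e-6)
  rpeaks((0:n) * ibi_ms / 1000, duration_s = duration_s)
}

# beat series whose instantaneous heart period is mean + depth*sin(2 pi f t)
sinus_rpeaks <- function(duration_s, mean_ms = 800, depth_ms = 40, freq_hz = 0.25) {
  m <- function(t) mean_ms + depth_ms * sin(2 * pi * freq_hz * t)
  rr_target_to_rpeaks(m, duration_s)
}

quiet_cohort_synchrony <- function(...) suppressMessages(cohort_synchrony(...))
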