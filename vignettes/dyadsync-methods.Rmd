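---
title: "Methods: dyadic cardiac synchrony estimation in dyadsync"
author: "dyadsync authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dyadic cardiac synchrony estimation in dyadsync}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadsync)
```

## The problem

When a parent and a child interact, their autonomic nervous systems do not
operate in isolation: heart rate and its vagally mediated component tend to
covary across partners, concurrently or with a short delay. `dyadsync`
quantifies this covariation from nothing more than each partner's R-peak
event times. Two per-second cardiac signals are derived per participant:

* **IBI** — the interbeat interval (ms), reflecting joint sympathetic and
  parasympathetic influence, and
* **RSA** — respiratory sinus arrhythmia, the natural log of the spectral
  power of the IBI series in the respiration band (0.12–0.40 Hz), a
  selective index of parasympathetic (vagal) activity.

Synchrony is the Pearson cross-correlation of the two partners'
pre-whitened series at integer lags from −3 to +3 s. Throughout the
package, **negative lags mean the child's signal precedes the mother's**
("child leads"); positive lags mean the mother leads. Positive correlations
mean the two physiologies move in the same direction.

## Per-second series

**IBI epoch means.** The interbeat interval is a step function of time: the
sample at time $t$ takes the value of the beat-to-beat interval containing
$t$, with the right-closed convention that the interval $(t_i, t_{i+1}]$
covers the samples in that span. The step function is sampled on a fixed
10 Hz grid anchored at recording start — both partners therefore share one
grid — and each second's ten samples are averaged into one epoch mean.
Epochs are half-open $[j, j+1)$ seconds, 0-based. An epoch that touches any
sample outside the peak span is invalid rather than partially averaged,
propagating missingness instead of diluting it.

**Second-by-second RSA.** The IBI sequence (each interval plotted at the
beat that closes it) is interpolated with a natural cubic spline onto a
4 Hz grid, making it equidistant. A sliding multitaper estimator then moves
over the series in 1-s hops: each 32-s (128-sample) segment is demeaned,
multiplied by each Slepian taper, Fourier transformed, the squared
magnitudes averaged across tapers, and the bins between 0.12 and 0.40 Hz
summed. The natural log of this band power, assigned to the window's centre
second, is the RSA value. The same band is used for adults and children.

Two numerical choices deserve a note:

* *Taper bank.* The default is $K = 3$ Slepian tapers at time–bandwidth
  product $NW = 2.5$ (`dpss_tapers()`), configurable. At 4 Hz and 128
  samples the concentration half-bandwidth is $2.5/32 = 0.078$ Hz. A
  fourth taper of this family is so weakly concentrated that a slow
  (0.05 Hz) oscillation would leak about 5–6 % of its power past the
  0.12 Hz band edge; with three tapers the leakage is below 1 %, which is
  why three is the default.
* *Window placement.* A 32-s window has no exact centre second. Windows are
  centred on each second's midpoint and, at the two edges of the recording,
  clamped inward by at most 2 s so that the boundary seconds nearest the
  margin still receive an estimate from the nearest full window. The first
  and final 15 s of a recording carry no estimate; a 300-s recording yields
  exactly 270 valid RSA seconds.
* $\ln(0)$ is guarded by an additive $\varepsilon = 10^{-12}\,\mathrm{ms}^2$,
  far below any physiological band power; it only matters for degenerate
  synthetic input.

## Pre-whitening and cross-correlation

Slow drift and within-person autocorrelation inflate naive
cross-correlations between any two physiological series. Each partner's
series is therefore pre-whitened independently before correlating:

1. **Second-order polynomial detrend** (`detrend_poly()`): least-squares
   removal of linear and quadratic trend.
2. **ARIMA(1,1,1) innovations** (`arima_prewhiten()`): a maximum-likelihood
   fit of one autoregressive term, one moving-average term and integrated
   noise, without a constant (the input is detrended and differenced, so a
   constant is not identifiable). The one-step-ahead innovation residuals
   are the whitened series; one sample is lost to differencing. If the fit
   does not converge the fall-back is an AR(1) on first differences,
   flagged in the report; a series constant after differencing returns
   all-zero residuals with a degenerate flag.

`cross_correlation_profile()` correlates mother residuals at time $t$ with
child residuals at $t + k$ for $k = -3 \dots +3$, each lag on its own
overlap of $n - |k|$ samples with per-lag re-centering — an unbiased
Pearson estimate per lag, with no zero padding or tapering of series ends.
Swapping the partners mirrors the profile, $r(k) \mapsto r(-k)$, which the
test suite asserts. For RSA, only the span valid in both partners enters
the pipeline; unequal residual lengths are truncated from recording start.

The test suite demonstrates why pre-whitening is not optional: for pairs of
mutually independent but strongly autocorrelated series (AR(1),
$\phi = 0.95$), the raw lag-0 correlation rejects a true null far above the
nominal rate, while the pre-whitened correlation holds it.

## Shuffled-pair surrogates

Partners doing the same task show similar signals for task-driven reasons
that have nothing to do with interaction. The surrogate control
(`shuffled_pair_profiles()`) recomputes the profile for the dyad's child
against **every** other mother, and the dyad's mother against every other
child, in the same condition, and averages the correlations per lag
(arithmetic mean over the pooled set; no Fisher transform by default, a
configurable choice). The set is exhaustive, never includes the own
partner, and involves no randomness, so surrogate values are
seed-independent. The per-dyad contrast *actual minus surrogate* is then a
paired test across the cohort.

## Affect cleaning

Binary per-second positive-affect series (from annotation intervals,
binarised by a 0.5-s coverage rule) can be regressed out of the raw
cardiac series before the synchrony pipeline
(`regress_out_affect()`): the design holds all 21 lagged copies of the
affect series (shifts −10…+10 s) jointly plus an intercept, with zero
padding for out-of-range shifts — zero is the meaningful "no affect" state
for a binary predictor, and padding preserves series length. Cleaning is
idempotent and never increases variance (it is a least-squares
projection); an all-zero affect series is an exact no-op.

Two variants exist: **individual** (each partner's own affect is removed
from their own series — the minimal reading; a both-partners design would
also be defensible) and **shared** (the AND of the two series, used for
both partners). The **shuffled-affect control**
(`shuffled_affect_control()`) repeats the cleaning with every other
same-role participant's affect series; if cleaning with one's *own* affect
reduces synchrony more than cleaning with someone else's, the reduction
reflects a genuine affect contribution rather than the generic variance
loss of removing 21 regressors.

## Group statistics

* `paired_t()`: dependent-samples t with listwise deletion; effect size
  defaults to $d_z = \bar d / s_d$ (configurable to $d_{av}$ — no single
  convention dominates the literature, so the formula is recorded in the
  output).
* `compare_lag_signs()`: paired tests of lag $-k$ versus $+k$, the
  child-leads/mother-leads asymmetry check.
* `condition_lmm()`: REML linear mixed model of synchrony on condition with
  a dyad random intercept (`lme4`), Satterthwaite degrees of freedom
  (`lmerTest`), marginal
  $R^2 = \sigma^2_f / (\sigma^2_f + \sigma^2_r + \sigma^2_e)$, and pairwise
  condition contrasts on estimated marginal means (`emmeans`).
* `fdr_adjust()`: Benjamini–Hochberg step-up, applied within families that
  mirror the analysis structure — across lags per condition and measure for
  the paired tests, across lags per measure for the mixed models, across
  the six contrasts within each model.

## The synthetic cohort generator

Real paired cardiac recordings of parents and children are rarely
shareable, so validation rests on `simulate_cohort()`, which generates
dyads with known ground truth. Per participant, the instantaneous heart
period is

$$m(t) = \mu + g\,\ell(t + L_{\text{role}})
       + A\,(1 + \gamma\,a(t))\,\sin(2\pi f_r t + \varphi)
       + \beta\,a(t) + \epsilon(t)$$

with baseline $\mu$ (850 ms adult, 700 ms child), a shared Ornstein–
Uhlenbeck latent $\ell$ (10-s timescale, unit variance) scaled by the
coupling gain $g$ and shifted by the coupling lag for the mother (negative
lag = child leads), a respiration-band oscillation ($f_r$ = 0.25 Hz adult,
0.30 Hz child; amplitude $A$ = 35 ms; per-participant random phase
$\varphi$), an affect-driven amplitude gain $\gamma$ and heart-period shift
$\beta$ (−40 ms during affect), and white per-second noise (SD 10 ms).
Beats follow the forward recursion $t_{i+1} = t_i + m(t_i)/1000$ — an
integral-pulse-style generator that is exact and fast at these modulation
depths. Affect $a(t)$ is a two-state Markov chain (stationary rate 0.10,
mean bout 4 s) for the leading partner; the follower imitates episodes
with probability 0.7 at the coupling lag. Coupling and imitation are
active only in the interactive conditions (La1, La2), mirroring a design
in which partners also rest and play alone.

Two calibration decisions are worth stating openly:

* **Reference gain.** The coupling gain default (80 ms per latent SD) was
  chosen, once, so that the injected lag is recovered as the profile's
  argmax in essentially all simulated dyads at 300 s. Group-mean peak
  synchrony is then ≈ 0.3 — larger than the 0.05–0.15 typically reported
  for real mother–child cohorts. A gain producing field-realistic means
  leaves too little power to localise the lag within a single 300-s dyad,
  so the generator favours a validation regime over a literal emulation of
  field effect sizes; the lag-0 values (≈ 0.05) do fall in the realistic
  range.
* **Null cohorts.** "Uncoupled" means both the latent gain *and* affect
  imitation are zero: imitated affect episodes shift both partners' heart
  periods and are themselves a coupling channel (lag-0 bias ≈ +0.07 with
  defaults if left on).

What the generator does **not** emulate: movement artefacts and ectopic
beats, a separate sympathetic (pre-ejection period) channel, respiration
rate drift or cross-frequency structure, negative affect, and real
missing-data patterns. Passing tests therefore show that the estimator
chain is correct under its own assumptions — stationary respiration-band
modulation, additive smooth coupling, clean R-peaks — not that every
real-data complication is handled.

## Problem sizes and tolerances used in validation

The validation suite runs the whole chain at sizes chosen to balance
statistical resolution against runtime: 300-s recordings throughout;
100 dyads for lag-recovery (≥ 90 % argmax criterion), 200 dyads and 50
replicate 8-dyad cohorts for null calibration (cohort mean within 2 SE of
zero; surrogate contrast non-significant in ≥ 90 % of null cohorts);
30 dyads for the cleaning contrasts; $n = 5000$ for ARIMA parameter
recovery (±0.05). Oracle comparisons (brute-force Pearson per lag,
step-up FDR, normal-equation least squares) are exact to numerical
precision.

## Known limitations

* R-peak detection and artefact correction are out of scope; the package
  expects clean event times and propagates invalidity rather than
  repairing it.
* The multitaper bank approximates the peak-matched multiple-window family
  used by some RSA tools; any orthonormal bank can be supplied through the
  `taper_bank` argument, and the family used is echoed in the metadata.
* With 300-s conditions, a 32-s window and lags of a few seconds, the
  method resolves *slow* covariation; it says nothing about beat-to-beat
  directionality.
* Mixed-model contrasts assume the per-dyad synchrony values are
  approximately normal; with $n \gtrsim 30$ dyads this is mild.
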