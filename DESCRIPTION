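Package: dyadsync
Title: Dyadic Cardiac Physiological Synchrony from Interbeat Intervals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimation of second-by-second interbeat-interval (IBI) and
    respiratory sinus arrhythmia (RSA) time series from R-peak event times,
    and lagged cross-correlation synchrony between two interacting partners
    after polynomial detrending and ARIMA pre-whitening. Includes exhaustive
    shuffled-pair surrogate nulls, lagged regression removal of micro-coded
    binary affect from the cardiac series, cohort-level inference (paired
    tests, mirrored-lag comparisons, condition mixed models with
    false-discovery-rate families), and a synthetic coupled-dyad generator
    with known ground-truth coupling for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    yaml,
    lme4,
    lmerTest,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
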