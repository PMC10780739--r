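---
title: "Methods: Kp-gradient analysis of the moss growth–temperature response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Kp-gradient analysis of the moss growth-temperature response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its statistical methods: the
models fitted, the conventions adopted where the field protocol leaves a
choice open, the design of the synthetic campaign generator, and the known
limitations of both.

## 1. From interval samples to daily paired records

Growth monitoring produces, per sample plot, a sequence of sampling
intervals with a mean shoot elongation rate (mm/day). The daily pattern is
built by carrying each interval's rate to every day in `(start, end]` —
growth accrues up to and including the sampling day. The protocol does not
dictate which endpoint owns the boundary day; the half-open convention
guarantees that abutting intervals tile the season without gaps or double
counting, and it conserves total growth (rate × length) exactly.

Plot patterns are averaged per date with an unweighted mean over the plots
reporting that date — no imputation, a date absent everywhere stays
absent. Smoothing (centered 3-day moving average) is applied *after* plot
averaging, to the mire-area pattern, because that pattern is the analysis
object; the window shrinks at season edges and never crosses the winter
gap. The alternative order (smooth per plot, then average) is a linear
operation away and differs only where plots have missing dates.

Three-hourly Kp is reduced to one value per complete UTC day (all 8
synoptic slots present; incomplete days are dropped with a warning). How
the 3-hourly index should become a daily value is genuinely unspecified in
the field protocol; the package defaults to the **mean** of the 8 slots
and exposes `max` as well (`daily_kp(aggregator=)`). The daily mean is the
smoother summary and keeps the daily series on the familiar 0–9 scale.

Causality is preserved by pairing the growth of day *d* with temperature
and Kp of day *d − lag*, `lag = 1` by default. Records lacking a driver
day are dropped and counted.

## 2. Correlations and the Kp gradient

All associations are Pearson correlations. Two-sided p-values come from
`t = r sqrt((n-2)/(1-r^2))` on `n − 2` df and are computed **in log10
space** via `pt(..., log.p = TRUE)`: with a thousand-plus records the
p-values of interest sit far below `1e-308` and would underflow double
precision if exponentiated.

For the gradient analysis the records are sorted by increasing Kp (stable
sort, ties broken by date so reruns are reproducible) and `r(growth,
temperature)` is computed in every window of 200 consecutive records, step
1, along with the window's mean Kp (median available by flag). The rolling
statistics use centered cumulative sums — values are globally centered
first, which keeps the cancellation error near `1e-14` for windows of this
size — and the test suite verifies every window against a direct
per-slice `cor()` to `1e-12`.

### Favorable-interval detection

The analysis flags the Kp region where the windowed correlation exceeds
the whole-data correlation (the *reference*). Reporting the maximal run of
flagged windows is tempting but poorly localized: the profile approaches
the reference level on its flat foot, so the first/last crossing ranks
wander widely between replicates. The package's default `"half_rise"` rule
instead delimits the contiguous region around the peak where the profile
stays above the level halfway between the reference and the **median**
correlation of flagged windows; the crossing then happens on the steep
flank of the rise. The median (not the maximum) estimates the elevated
plateau: anchoring the level to the noisy peak biases the boundaries
inward. The plain `"run"` rule remains available
(`detect_favorable_interval(rule = "run")`). On default synthetic
campaigns the half-rise rule recovers the injected window boundaries to
0.25 Kp units in the large majority of seeded replicates (the acceptance
suite quantifies this).

The share of favorable days is the percentage of monitoring days whose
day-prior Kp falls in the closed interval, rounded half-up to one decimal
— half-up is also used for the monitoring bookkeeping means, matching how
such tables are conventionally rounded.

### Null envelope, and a calibration caveat

`permutation_envelope()` re-randomizes the Kp column against the fixed
(growth, temperature) pairs and rebuilds the window profile, giving a
pointwise 2.5/50/97.5% envelope. Two schemes are provided:

* `"permute"` (default): a fresh permutation of the Kp values. This treats
  records as exchangeable. Kp, however, is strongly autocorrelated in
  time, so days of similar Kp cluster in calendar time and the *observed*
  sorted windows contain temporally clumped pairs; their correlation
  drifts at low frequency in a way an exchangeable null cannot reproduce.
  The permutation envelope is therefore somewhat anti-conservative, and a
  null profile should be expected to leave it more often than the nominal
  5% of windows.
* `"shift"`: a random circular rotation of the date-ordered Kp column.
  This preserves the Kp series' own autocorrelation, and under the null of
  no modulation the observed profile is exchangeable with the shift
  replicates, making this the better-calibrated choice.

Even with an exactly valid null, note that adjacent windows share 199 of
200 records: excursions come in long episodes, so the *fraction* of
windows outside the envelope is a heavy-tailed statistic across
replicates. Significance of a detected interval is therefore judged by
whether the profile escapes the envelope's upper band inside the interval,
not by overall coverage.

## 3. Detrending

Growth exists only within growing seasons, so its seasonal component is a
second-order polynomial in day-of-season fitted per season by OLS;
residuals retain their dates and season ids. Whether the original protocol
fitted one quadratic per season or per year is not documented; per season
is the only option that does not extrapolate across the winter gap. A
season needs at least 4 days to leave a residual degree of freedom.

Temperature's seasonal component is a single sinusoid plus offset, fitted
as linear least squares on `{1, sin(2πt/P), cos(2πt/P)}` with `t` in days
from the series start; the default period is 365.3 days and
`scan_period()` reproduces the selection of the best period by R² over a
grid (ties to the smaller period). Amplitude is `sqrt(s² + c²)` and phase
is reported as the peak day. Degenerate inputs behave sensibly: a constant
series yields amplitude 0 with R² defined as 1 (zero total sum of
squares means the trivial fit is exact), and a span shorter than one
period triggers a warning rather than an error.

## 4. The synthetic campaign generator

The generator emulates the monitoring design — by default 8 consecutive
seasons (day-of-year 110–290), 6 plots, 2-day sampling intervals, 40
shoots per sample — with drivers generated for one extra day before each
first season day so day-prior alignment never truncates.

**Kp.** A stationary Gaussian AR(1) latent series on the 3-h grid
(`kp_ar_rho = 0.8`) is probability-transformed to a gamma marginal (shape
`kp_skew = 1`, mean `kp_level = 1.5` — right-skewed, most daily means well
below 3), clipped to `[0, 9]` and snapped to the published thirds grid
(ties up). The shape/mean split exists because a single "skew" knob cannot
fix both the skewness and the level of the marginal.

**Temperature.** Daily mean = 4 °C + 12 °C annual sinusoid (period 365.3
d, peak late July) + stationary AR(1) noise (marginal SD 3 °C, lag-1 0.7).
The diurnal value at synoptic hour *h* adds a deterministic within-day
sinusoid (amplitude 4 °C, warmest mid-afternoon) **plus an hour-specific
anomaly** (SD 2.5 °C, AR(1) across days within each hour, independent
across hours). The hour-specific term is essential: without it every
hour's anomaly would equal the daily anomaly and the eight diurnal rows
would be mathematically identical, leaving nothing for the diurnal
analysis to resolve. Real hourly weather anomalies are persistent across
days (cold mornings come in spells), which the AR(1) structure captures;
their cross-hour correlation within a day is *not* modeled, which makes
the hours more distinguishable than in real data.

**Growth.** The true mire rate on day *d* is
`max(0, hump(d) + beta(Kp_{d-1}) * anom_{d-1} + process noise)`, with a
quadratic seasonal hump (peak 4 mm/day, zero at the season edges), the
hour-weight-averaged temperature anomaly as driver, and
`beta(Kp) = beta0 (1 + kappa)` inside the injected Kp window `[0.9, 1.6]`
(`beta0 = 0.15` mm/day/°C, `kappa = 1`). Daily process noise (SD 0.3
mm/day) is shared across plots, while per-shoot noise (SD 1.5 mm/day,
scaled by the square root of the interval length) is averaged over shoots
and plots — so multi-plot averaging genuinely reduces variance, as in the
field design. Emitted plot rates are floored at zero, like real
elongation measurements.

**What passing tests do and do not show.** The generator reproduces the
*structure* of the campaign (sampling, seasonality, autocorrelation,
skewed Kp, day-prior coupling), not its calibration: no distributional
facts about the real mire series are available, so all generator defaults
are plausible stand-ins. Recovery of the injected window demonstrates
that the pipeline can detect a modulation of this form and magnitude at
this sample size — not that the real data's interval is correct, nor that
real noise (moisture limitation, instrument drift, spatially correlated
weather) would be equally benign.

## 5. Validation problem sizes

The seeded validation suite uses 20 replicates of the default campaign
(≈1440 mire-area records each, matching the scale of an 8-season
campaign), sliding windows of 200 records, and permutation envelopes of
100–200 replicates; unit tests use 2-season campaigns. These sizes keep
the full suite fast while leaving the recovery statistics at the scale the
analysis targets.

## 6. Known limitations

* No gap imputation and no reconstruction of shoot-level raw measurements;
  inputs are taken at the interval-table level.
* The daily Kp aggregation (mean by default) is a convention, not a fact;
  results near the interval boundaries can shift slightly under `max`.
* The exchangeable permutation envelope is anti-conservative under
  autocorrelated Kp (see §2); use `method = "shift"` when calibration
  matters.
* The detection rule assumes a single contiguous favorable interval; a
  profile with two disjoint elevated regions returns only the one holding
  the global peak.
* Soil-surface versus air temperature is a data contrast, not a method
  change: run the same pipeline on a second temperature file.
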