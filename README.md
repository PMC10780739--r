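# kpgrowth

Analysis pipeline for studying how the geomagnetic Kp index modulates the
temperature growth response of peat moss (*Sphagnum riparium*) in long-term
mire monitoring campaigns — plus a synthetic campaign generator with known
ground truth so every stage can be validated end to end.

## The scientific problem

Field monitoring of fast-growing peat moss yields plot-level shoot
elongation rates over ~2-day sampling intervals across April–October
seasons. Moss growth responds strongly to temperature; the question is
whether the strength of that response changes with the planetary
geomagnetic disturbance index Kp (eight values per UTC day on a 0–9 scale
in thirds). The package implements the full analysis chain:

1. **Pattern construction** — each interval's mean rate (mm/day) is
   extrapolated to the days `(start, end]`, plots are averaged per date
   into a mire-area pattern, and the pattern is smoothed with a centered
   3-day moving average within each season.
2. **Day-prior alignment** — the growth rate of day *d* is paired with the
   temperature and daily Kp of day *d − 1* to preserve causality, giving
   records (GR_d, T_{d−1}, Kp_{d−1}).
3. **Global correlations** — Pearson *r* of growth vs temperature and
   growth vs Kp, with two-sided p-values from
   *t* = *r*·sqrt((*n* − 2)/(1 − *r*²)) kept in log10 space so values far
   below double-precision underflow remain exact.
4. **Kp-gradient sliding window** — records are sorted by increasing Kp
   and *r*(GR, T) is computed in every window of 200 consecutive records
   together with the window's mean Kp, tracing the temperature response
   along the Kp gradient.
5. **Favorable-interval detection** — the contiguous Kp region whose
   windowed correlation exceeds the whole-data level, delimited where the
   profile crosses halfway up its rise (see the vignette), plus the
   percentage of monitoring days falling inside it.
6. **Detrending** — a per-season second-order polynomial is removed from
   growth and a 365.3-day sinusoid (selectable by an R² period scan) from
   temperature; the gradient analysis is repeated on the residuals.
7. **Diurnal profiling** — steps 2–4 are repeated against the temperature
   at each synoptic hour (00, 03, …, 21 h) and the morning/evening
   bimodality of the per-hour response profile is scored.
8. **Null calibration** — a permutation (or circular-shift) envelope for
   the window profile under "no Kp modulation".

Because the original mire data are not deposited, the `synth` module
generates campaigns with the same structure (AR(1) weather noise on an
annual harmonic, right-skewed autocorrelated Kp on the thirds grid,
interval sampling over plots and shoots) and a known coupling: the
growth–temperature slope is `beta0·(1 + kappa)` on days whose prior-day Kp
lies in a configurable window, `beta0` otherwise. Recovery of that window
is the package's core validation.

## Worked example

```r
library(kpgrowth)

cfg <- pipeline_config(synth = synth_config(seed = 1), seed = 1)
res <- run_pipeline(cfg)
print(res)
```

```
Kp-gradient growth-temperature analysis
-------------------------------------------------------
paired records: 1440 (dropped 0 without day-prior drivers)
growth ~ temperature (all data): r = 0.904 (n = 1440; log10 P = -532.8)
growth ~ Kp (all data): r = 0.023 (n = 1440; log10 P = -0.4)
growth ~ temperature (detrended residuals): r = 0.771 (n = 1440; log10 P = -283.2)
temperature harmonic: period 365.3 d, amplitude 12.20 degC, R^2 = 0.894
subrange Kp < 0.87: r = 0.874 (n = 456; log10 P = -143.7)
subrange Kp 0.87-1.61: r = 0.930 (n = 421; log10 P = -183.6)
subrange Kp > 1.61: r = 0.907 (n = 563; log10 P = -212.1)
favorable Kp interval: [0.99, 1.70], peak r = 0.943 at Kp = 1.32; 26.7% of monitoring days inside
envelope coverage of observed profile: 59.1% of windows (n_perm = 200)
diurnal bimodality score: 0.0268 (morning 0.842, evening 0.804, midday 0.797)
```

Reading the output: growth tracks temperature strongly overall but shows no
direct Kp response (r ≈ 0.02); the sliding-window profile still rises above
its whole-data level in a narrow Kp band — here detected as [0.99, 1.70],
overlapping the injected ground-truth window [0.9, 1.6] — and the boosted
coupling pushes the observed profile outside the null envelope there (the
59% coverage reflects the injected modulation; a `kappa = 0` campaign sits
near 95%). With uniform hour weights the diurnal profile is flat and the
bimodality score is near zero.

Set `out_dir` in `pipeline_config()` to write every stage's CSV/JSON
artifacts plus a plain-text summary; `write_campaign()` exports a synthetic
campaign in the standard input schemas.

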