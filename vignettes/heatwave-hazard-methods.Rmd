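---
title: "Methods: torridity-index heatwave detection and hazard assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: torridity-index heatwave detection and hazard assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(torrid)
```

## Scope and assumptions

`torrid` assesses heatwave hazard from two daily inputs over the extended
summer (May 1 – September 30, always 153 days; leap years do not change the
window): maximum temperature MT (°C) and mean relative humidity RH (%). The
pipeline assumes

* days within a season are comparable after local threshold calibration —
  the threshold is a property of the location, not of the year;
* pixels (or stations) are independent: no spatial pooling, smoothing or
  borrowing of strength happens anywhere in the pipeline;
* hazard is fully described by frequency, intensity and duration of events;
  exposure and vulnerability are out of scope.

## The torridity index and its threshold

`torridity_index()` maps (MT, RH) to
`TI = 1.8·MT − 0.55·(1.8·MT − 26)·(1 − r) + 32` with `r = max(RH/100, 0.6)`.
The humidity factor is pinned at 0.6 below 60 % RH: in dry air the apparent
heat is governed by temperature alone, and the two branches join continuously
at 60 %. TI is treated as a dimensionless index (its ×1.8/+32 structure puts
it on a Fahrenheit-like scale); nothing downstream depends on its units, only
on differences TI − TI′.

`ti_threshold()` pools, per pixel, every day with MT > 33 °C across **all**
years and takes the quantile (default p = 0.5) of their TI as the local
threshold TI′. Design choices here:

* **All years pooled, one TI′ per pixel.** A fixed threshold is what makes
  hot-day status, and hence the normalized hazard, comparable from year to
  year. A per-year threshold would absorb exactly the trend signal the
  pipeline is meant to measure.
* **Quantile definition.** `quantile_paper()` uses the one-third
  plotting-position rule `h = p·n + (1+p)/3`, `j = ⌊h⌋`, `γ = h − j`,
  interpolating `(1−γ)X(j) + γX(j+1)` on the ascending sort (this is the
  approximately median-unbiased type-8 definition). At the boundaries the
  index formula can fall outside `[1, n−1]`; the nearest order statistic is
  returned (`X(1)` or `X(n)`). That boundary rule is ours — no rule is
  implied by the formula itself — and only matters for extreme p at small n,
  never for the median of a usable sample.
* **`min_samples` (default 10).** A median of fewer than ~10 hot days is too
  unstable to anchor a threshold; pixels below the floor are flagged invalid
  and excluded from detection rather than silently zero-filled. Cool-climate
  pixels therefore *have no defined heatwave hazard* instead of a spurious
  zero threshold.

## Daily heat index and event definition

On a hot day (TI ≥ TI′; equality counts as hot — the event definition is an
inequality with ≥, and ties have measure zero on continuous data)
`heat_index_day()` computes

`HI = 1.2·Δ₀ + 0.35·Σᵢ₌₁..ɴ Δᵢ/i + 0.15·Σᵢ₌₁..ɴ₋₁ 1/(i+1)`

where N is the number of *immediately preceding consecutive* hot days in the
same season, Δᵢ the exceedance i days back, and the lag weight 1/i encodes
days of separation from the current day. The third term is implemented
exactly as written: a pure persistence bonus depending only on run length,
with no temperature factor. (One could suspect a missing Δ factor there; we
keep the printed form — the term is small, bounded by 0.15·(H_N − 1), and a
temperature-weighted variant would change HI by well under the 2.8 decision
threshold for realistic runs.) Lag terms never cross a non-hot day or the
September→May gap.

`detect_events()` keeps maximal hot runs with length ≥ 3 days and event index
HWI ≥ 2.8. **HWI is the mean of the run's daily HI by default.** The 2.8
cutoff is a daily heat grade ("the day reaches heatwave standard if
HI ≥ 2.8"), which is only commensurable with an average of daily grades; a
plain sum (`hwi_mode = "sum"`) is also provided, and the two are related by
HWI_sum = N·HWI_mean, so the sum mode with the same cutoff is strictly more
permissive. Events are attributed to the calendar year of their start date;
runs cannot bridge seasons, so start-year attribution is unambiguous except
for runs touching September 30, which belong to the year they started in.

Annual indicators per pixel-year: HWF (count of events), HWMHI (maximum daily
HI across the year's events, running-max update), HWMD (longest duration).
Eventless pixel-years are zeros.

## Hazard, trends, relative change

`normalize_indicators()` divides each indicator by a single **domain-wide
maximum** (all pixels, all years). The alternative — per-pixel maxima — makes
every pixel's best year look equally extreme and destroys spatial
comparability of the resulting maps; it is available as
`scope = "pixel"` for sensitivity analysis. `hazard_score()` is the
equal-weight mean of the three normalized indicators: hazard ∈ [0, 1], equal
to 1 only where all three maxima coincide, 0 where no heatwave ever occurs.

`trend_surface()` fits per-pixel OLS of annual hazard on year with a
two-sided t test at α = 0.05 (no autocorrelation correction; annual hazard
values are treated as exchangeable residuals around the trend). Constant
series get slope 0, R² 0, p 1 — a deliberate convention so masked-out oceans
or hazard-free pixels never appear significant.

`relative_change()` computes RC = (L̄Y − F̄Y)/overall mean with five-year
windows at either end (configurable). RC is scale-invariant and unit-free;
RC > 0.8 is read as a sharp increase. When grouping by region or month, the
series is averaged over the group **first** and RC applied to the group-mean
series.

## Classification and zoning

`jenks_breaks()` is exact Fisher–Jenks: dynamic programming over the sorted
values, O(k·n²), minimizing total within-class squared deviation —
deterministic, unlike the Jenks–Caspall reassignment heuristic. Class
intervals are right-closed (a value equal to a cut falls in the lower class);
every finite value gets exactly one of the k labels.

Spatial classes (k = 5: low … high) are fitted on AH. Temporal classes
(k = 5: decreased … increased) are fitted on the trend slopes of pixels
passing the significance mask; non-significant pixels are labelled
"basically unchanged" — absence of evidence for a trend is treated as no
trend, which biases the temporal map conservatively.

The 5 × 5 label cross maps to four categories via a table
(`default_category_table()`): category 1 ("high hazard and rapidly
increasing") = {high, medium-high} × {increased, slightly increased};
category 2 = {high, medium-high} × the remaining trend bands; category 3
("low hazard and continually increasing") = {middle, medium-low, low} ×
{increased, slightly increased}; category 4 = others. Placing *middle* with
the low band in category 3 follows the reading that category 3 covers the
bulk of mid-hazard increasing area; because the exact band assignment of a
published figure of this kind is rarely fully enumerable, the table is an
argument and can be overridden cell by cell.

`zonal_statistics()` assigns a pixel to a zone when its centre falls inside
the polygon (`mgcv::in.out`): simple, reproducible, and adequate when zones
are large relative to the cell size. Zone ranks (descending AH, descending
slope) are permutations of the valid zones; ties are broken by zone order.

## The synthetic generator

`synthetic_climate_grid()` emulates the features of summer station/grid data
that the detector is sensitive to:

* a smooth seasonal cycle (half-sine over the 153-day window, default
  baseline 26 °C, amplitude 7 °C, so the seasonal mean peaks at 33 °C — a
  mid-latitude hot-summer climate in which MT > 33 °C days are common but
  not constant);
* day-to-day persistence: AR(1) anomalies (default φ = 0.7, stationary sd
  2.5 °C), restarted each season — heat builds over consecutive days, which
  the HI's lag terms reward;
* humidity as a clipped Gaussian (mean 60 %, sd 8 %) linearly coupled to the
  temperature anomaly (default −2 %/°C: hot spells are dry spells), so both
  branches of the TI formula are exercised;
* injected episodes: MT on episode days is raised to at least 40 °C plus
  `exceedance/1.404` (1.404 index/°C is the dry-branch TI slope), which
  guarantees the day's TI clears any attainable TI′ by at least the
  configured margin; one guard day on each side is capped at 26 °C
  (TI ≤ 78.8, below the 84.05 floor of any valid TI′) so the injected run's
  boundaries are unambiguous. Episodes *add* to the background rather than
  replacing the RNG stream, so an episode-free run with the same seed has
  the identical background, and overlapping or contiguous injections are
  merged in the truth catalog because they form one uninterrupted run.

What it does **not** emulate: spatial correlation (pixels are independent),
synoptic-scale weather systems, elevation effects, observational gaps, or
interpolation artefacts. Passing recovery tests therefore demonstrates the
correctness of the detection logic under realistic temporal structure — not
robustness to spatially coherent noise or data quality problems in real
networks.

The background climate generates genuine heatwaves of its own (the seasonal
peak sits at the hot-sample cutoff), so recovery tests run against a
non-trivial event population: exact recovery means the injected events are
found *among* hundreds of natural ones with exactly matching year, start and
duration, not merely that "something" was detected.

## Problem sizes and numerical conventions

The test suite exercises: quantile agreement with a literal brute-force
oracle on all 3002 sorted multisets of length ≤ 10 over a 5-symbol alphabet
× 9 quantile levels; run detection against enumeration on all 4096 12-day
masks; Fisher–Jenks against exhaustive split-point search on 1000 sampled
sequences (n ≤ 12, k ≤ 4); episode recovery on a 20 × 20 pixel, 30-year grid
with 50 true episodes and 30 sub-threshold decoys; and trend recovery with
500 noisy-slope and 1000 null replicates. These sizes make the whole suite
run in well under a minute while keeping every enumeration exhaustive over
its stated domain.

Numerical conventions collected in one place: RH enters the TI formula as a
fraction; hot-day comparison is ≥; quantile boundary clamps to the nearest
order statistic; 0/0 in indicator normalization is 0; constant series have
slope 0/R² 0/p 1; natural-breaks intervals are right-closed; non-significant
trend pixels are "basically unchanged"; zone membership is by pixel centre;
rank ties break by zone order.

## Limitations

* The TI uses temperature and humidity only — no wind, radiation, or
  acclimatization terms; alternative apparent-temperature scales (WBGT,
  humidex, UTCI) are out of scope.
* Equal indicator weights are a modelling choice, not an optimum.
* Trend inference ignores serial correlation between years.
* Compound or interrupted ("sequential") heatwave metrics are not computed;
  a one-day cool interruption splits an event in two.
* Hazard is one factor of risk; exposure and vulnerability layers must come
  from elsewhere.
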