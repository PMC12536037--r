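---
title: "Methods: personal PM2.5 exposure assessment with pmtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: personal PM2.5 exposure assessment with pmtrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pmtrace)
```

`pmtrace` turns minute-level streams from a wearable optical particle
sensor with GPS into microenvironment-resolved personal PM2.5 exposure
estimates and mixed-model inference. This vignette explains the model and
procedure behind each stage, the tunable parameters and their defaults,
what the synthetic-data generator does and does not emulate, and the
numerical choices made where the design was genuinely open.

## The measurement problem

A low-cost light-scattering sensor logs, every minute: counts of particles
above 0.3/0.5/1/2.5/5/10 µm, mass concentrations below 1/2.5/10 µm
(µg/m³), temperature, relative humidity, and a GPS fix. The mass channel is
a proprietary transform of the count spectrum and is biased relative to
reference monitors; the bias is well described as linear over the ambient
range. GPS fixes carry metre-scale noise and drop out (indoors especially).
The analysis must therefore (i) clean the stream, (ii) decide *where* the
wearer was — which land-use parcel, indoors or outdoors, or in a vehicle —
from GPS alone, (iii) correct the mass channel against regulatory
monitors without any laboratory collocation, and (iv) summarise exposure
and apportion inhaled dose across microenvironments before fitting an
explanatory model.

## Preprocessing

Two filters run in order, each appending a row to a stage-accounting
ledger. Percentages in the ledger are always relative to the **raw** total,
so successive rows read like a flow chart of the original record count.

* *Invalid records*: a record is dropped when its participant id,
  timestamp, or any of the nine pollution channels is missing
  (`rule = "any"`; the stricter reading, all nine missing, is available as
  `rule = "all"` because field formats differ in whether a partial row can
  occur). A record with pollution data but no GPS fix is **kept**: it still
  informs overall exposure, only the context stage needs coordinates.
  Duplicate (participant, timestamp) pairs keep the first occurrence and
  are counted in a diagnostic rather than the ledger, since they are a
  logging artefact rather than a data-quality signal.
* *Zero participants*: a participant is removed when the fraction of their
  records with all nine channels simultaneously zero is **strictly**
  greater than 0.99. The strict inequality reads "over 99%" as exceedance;
  a participant at exactly 99.0% is retained.

Both filters are idempotent, preserve record order, and satisfy the closure
`sum(dropped) + remaining = raw` by construction.

## Context identification

All metric computation happens in a local tangent-plane projection about
the region centroid (`x = R·cos(lat₀)·Δlon`, `y = R·Δlat`): degree-space
distances are anisotropic, and at study scales below ~50 km the
tangent-plane approximation is exact to well under 1% (the test suite
cross-checks it against geodesic distances). The projection is exactly
invertible, which the generator relies on.

The stage runs five steps, with defaults chosen once and exposed in
`context_params()`:

1. **Median smoothing** (window 5 fixes, shrunk at track edges). A moving
   median suppresses isolated multipath spikes without lagging the track.
   Gap minutes stay missing and are skipped when forming neighbours'
   windows.
2. **Imputation** (`max_gap` 10 min). Gaps up to 10 minutes are filled by
   linear interpolation of the projected coordinates against time — the
   right model for both stationary periods and constant-speed trips.
   Longer gaps are excluded from context analysis but remain in the
   overall exposure stream.
3. **Stay/trip segmentation** (`eps` 30 m, `min_duration` 5 min,
   `max_time_gap` 10 min). A stay is the longest temporally contiguous
   prefix window, from an anchor fix, in which every member lies within
   `eps` of the window's centroid; windows spanning at least
   `min_duration` minutes become stays, remaining fixes form maximal
   contiguous trips, and contiguity breaks at time gaps over
   `max_time_gap`. The implementation re-verifies the whole window on each
   extension; an exhaustive from-scratch enumeration in the test suite
   confirms exact agreement on hundreds of random tracks. `eps` must
   comfortably exceed GPS noise (30 m vs ~5–10 m) while staying below the
   distance travelled in one minute at walking speed (~84 m), which is
   what makes noiseless recovery exact.
4. **Stay labelling**. Each stay takes the class of the nearest land-use
   polygon (distance 0 when inside one; ties break to the smallest feature
   index for determinism). Indoor/outdoor is decided by whether the stay
   *centroid* falls within 10 m of any building footprint — the centroid,
   not each fix, because averaging cancels jitter; the 10-m buffer absorbs
   residual GPS error at the cost of occasionally capturing a doorstep.
   Stays whose centroid falls outside the study region are excluded and
   counted. Enlarging the buffer can only flip outdoor→indoor, never the
   reverse.
5. **Trip modes** (`speed_threshold` 2.5 m/s, `distance_threshold` 500 m).
   Per-trip features are the mean and standard deviation of fix-to-fix
   speeds and the path length; a trip is vehicle-based iff mean speed
   exceeds the threshold, or the path exceeds 500 m and mean+sd speed
   does. Vehicle minutes are labelled (`vehicle`, indoor) — a cabin is an
   enclosed microenvironment; walking minutes are outdoor and take the
   nearest land-use class *per minute*, since a walk can cross parcels.

Finally the **valid-day filter** removes participant-days (local calendar
days; the study timezone defaults to the fixed-offset zone `Etc/GMT+8` and
any IANA zone is accepted, with DST handled by the platform's timezone
database) carrying strictly less than 6 hours of labelled minutes, so
time-budget and dose shares are not distorted by fragmentary days.

## In-situ calibration

Laboratory collocation does not scale to a fleet of personal monitors, so
the calibration exploits the context labels: for every (participant, UTC
hour) with at least 30 outdoor-labelled minutes, hourly means of the raw
mass channel, RH, temperature and position are paired with the **nearest**
regulatory station, provided it lies within a cut-off distance and reports
that hour. The model is

```
reference ~ raw + rh + temp + (1 | participant)
```

fitted by REML. RH and temperature enter because optical scattering is
humidity-sensitive and the device logs both; their coefficients recover
zero when the generator's distortion ignores them. When the random
intercept is estimated at exactly zero (common when stations measure the
shared field without error) the fit is singular and the model falls back
to ordinary least squares with a warning flag — same fixed effects, honest
diagnostics. The cut-off is scanned over {0.5, 0.6, 0.75, 1, 1.5, 2, 3, 4,
5} km (the grid dips below the classical 0.5 km floor so a 600-m operating
point is expressible) and the cut-off maximising R² is selected, ties going
to the smallest distance — nearer stations can only share the airshed
better. Calibrated minutes are **fixed-effects-only** predictions: random
intercepts are identified only for the collocated subset and would not
generalise; negative predictions are floored at zero and counted.

With mean-one multiplicative sensor noise of σ = 0.2 per minute, hourly
averaging over ≥30 minutes leaves ~3% noise on the pair predictor, so
attenuation bias on the recovered slope is a fraction of a percent — the
recovery suite measures median absolute slope error below 1%.

## Exposure metrics

*Summaries* use the linear-interpolation percentile rule (type 7), stated
explicitly because percentile conventions differ. *Dose* in
microenvironment *k* is `breathing_rate × Σ conc × 1 min` (µg); the rate
defaults to 0.012 m³/min, and because it is a constant, dose *proportions*
are invariant to it — under spatially uniform concentrations they equal
time fractions exactly. *Home-address reconstruction* uses inverse
distance weighting with power 2 over all stations within 50 km (weights
sum to 1 per hour; a station at the home returns its own series; hours with
no in-radius station are missing and counted). *Personal-vs-home
comparison* reports Pearson correlations at both the minute and the hourly
scale — aggregation smooths indoor spikes and inflates r, so both are
informative — and the P/O ratio per participant as the ratio of period
means, not of minute ratios, which explode when the denominator nears
zero. Seasons are meteorological (Mar–May spring, etc.) in local time.

## Inference

Subgroup comparisons use rank tests (exposure distributions are heavy-
tailed): Wilcoxon for two groups, Kruskal–Wallis for three or more with
Bonferroni-multiplied pairwise post-hocs when the omnibus test is
significant. Midranks with tie correction are used throughout; the test
suite checks the statistic against its rank-sum definition and against the
exact permutation distribution for n ≤ 10.

The spatiotemporal mixed model regresses calibrated minute PM2.5 on land
use (reference "other"), indoor/outdoor (reference outdoor) interacted
with the IDW home background, season (reference spring), local hour
(reference 0), and demographic covariates, with a participant random
intercept. Design columns with a single observed level are dropped with a
message (small cohorts cannot support every factor); genuinely aliased
columns raise an error naming them. Confidence intervals are Wald by
default and profile likelihood on request (`ci = "profile"`, optionally
restricted to named terms — profiling every coefficient of a wide model is
rarely worth the cost). P-values use the Satterthwaite approximation, or a
normal approximation for very large fits, and are BH-adjusted across **all
non-intercept fixed effects** — the family chosen here since the model is
reported as one table. EMMs average the prediction over the levels of the
other factors with equal weights, hold the background covariate at its
observed mean, and set random effects to zero; on balanced designs they
reduce to group means (verified to 1e-8). The indoor-stratum background
slope is the main effect plus the indoor×background interaction.
`indoor_slope()` also accepts a plain coefficient table, so published
results tables can be queried the same way.

The ICC comes from an intercept-only random-intercept model,
`var_between / (var_between + var_within)`; a singular fit reports 0 with a
flag. Land-use Shannon entropy `H = −Σ pᵢ ln pᵢ` is computed over land-use
time fractions with the vehicle class included by default (configurable,
as conventions differ). Sensitivity analyses refit the model with no
demographics, age+sex, and the full set, and run a seeded 10-group
leave-one-group-out, flagging refits that lose a factor level.

## The synthetic world

`simulate_study()` builds a complete study with ground truth at every
level. Its defaults are the package's study conditions, chosen once:

| parameter | default | rationale |
|---|---|---|
| cohort | 168 × 14 days | a two-week regional monitoring campaign |
| indoor time target | 0.78 | typical adult indoor fraction |
| residential time target | 0.67 | dominant home occupancy |
| ambient field | 6 + 3·cos(2π·doy/365) + 2·cos(2π·(h−19)/24), AR(1) φ=0.7 σ=1, floor 1 µg/m³ | winter/evening maxima over a clean-region baseline |
| infiltration | 0.6 | mid-range for closed dwellings |
| cooking | triangular pulse, peak 19:00, mean 15 µg/m³, lognormal day-to-day | dinnertime source |
| winter heating | +3 µg/m³ indoors at home | residential heating season |
| sensor distortion | ref = 0.5·raw + 2.0, lognormal σ=0.2 (mean-one) | optical-counter bias and heteroscedasticity |
| GPS | σ = 5 m, 2% gaps | consumer receiver outdoors |
| trips | straight lines, walk 1.4 m/s, vehicle 12 m/s | simplest kinematics separating the modes |
| breathing rate | 0.012 m³/min | constant; dose proportions are invariant to it |

Schedules are built day by day — home overnight, a weekday indoor
destination, a park visit sized so the realized indoor fraction lands on
target, evenings at home — with trips walked when the park is within 600 m
and driven otherwise. Stations report the regional ambient field without
error, which deliberately isolates calibration error to the sensor model;
stations can instead be flagged as a *detached airshed* (an independent
series), the construction behind `world_decorrelated_stations()` used to
show the cut-off scan prefers sub-kilometre pairings. Indoor source
magnitudes are free configuration, not calibrated to any cohort: no public
distributional parameters exist for them.

What the generator does **not** emulate — and hence what passing recovery
tests do and do not show — includes real urban morphology (parcels are a
grid), meteorology-driven dispersion and spatial concentration gradients
(the ambient field is regionally uniform), wildfire episodes, twin-pair
behavioural correlation, device drift, and GPS urban-canyon bias (noise is
isotropic and independent). Recovery at 100%/≥85% therefore validates the
*algorithms* under controlled error processes, not field performance of
any particular device.

## Numerical choices and degenerate inputs

Determinism is end-to-end: every stochastic choice derives from one seed
via fixed sub-seed keys, so identical (seed, config) reproduce identical
streams, and two pipeline runs hash to identical output trees. Validation
studies in the tests and the acceptance script use deliberately small
problem sizes — cohorts of 2–6 participants over 2–4 days for pipeline
properties, 40 participants × 3 days at 6 hour-bins with 20 seeds for the
coverage study, 10 seeds × 2000 pairs for calibration recovery — sizes at
which each check's statistical behaviour is already stable. Degenerate
inputs fail loudly and early: zero-area regions, empty land-use layers,
invalid geometries (named by feature), windows shorter than a visit,
zero-duration trips (dropped with a warning), zero total dose, constant
series in correlations (flagged), and missing interaction terms in
`indoor_slope()`. Nearest-feature ties break to the smallest index;
negative calibrated concentrations floor at zero and are counted rather
than silently clipped.

## Known limitations

The indoor test uses the stay centroid, so a stay straddling a doorway is
classified all-or-nothing. Mode classification is binary (no transit
subtypes) and map-matching is out of scope. The calibration assumes a
single static linear distortion — no drift, no per-channel count
calibration, no RH-sigmoid correction. The mixed model treats participants
as exchangeable random intercepts; twin-pair nesting is deliberately not
modelled. IDW is the only home-exposure interpolator offered; kriging and
land-use regression are out of scope.
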