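# pmtrace

Personal PM2.5 exposure assessment from wearable low-cost optical sensors
and GPS.

Epidemiological studies usually assign each person the ambient PM2.5
concentration interpolated to their home address. That misses what people
actually breathe: most time is spent indoors, where cooking, heating and
infiltration decouple exposure from the outdoor background, and the rest is
spread over offices, shops, parks and vehicles. `pmtrace` implements the
full analysis chain for minute-resolution personal monitoring campaigns in
which participants wear a device logging six particle-count channels, three
mass channels, temperature, relative humidity and a GPS fix every minute:

1. **Preprocessing** — record-level filters (missing id/timestamp/pollution
   channels; GPS missingness never drops a record) and removal of
   participants whose particle channels are all-zero for more than 99% of
   their record, with a stage-accounting ledger whose percentages always
   reference the raw total.
2. **Context identification** — moving-median GPS smoothing, linear
   imputation of gaps up to 10 min, stay/trip segmentation (temporally
   contiguous clusters whose fixes stay within `eps` of the running
   centroid for a minimum duration), microenvironment labelling by the
   nearest land-use polygon (7 classes + "other"), an indoor flag from a
   10-m building buffer, trip-mode classification from speed and path
   length (vehicle trips count as indoor, walking trips as outdoor), an
   out-of-region exclusion, and a 6-hour valid-day filter.
3. **In-situ calibration** — opportunistic collocation: hours with at least
   30 outdoor-labelled minutes are paired with the nearest regulatory
   station within a cut-off distance; a linear mixed model (reference ~ raw
   + RH + temperature + participant random intercept, REML) is fitted over
   a 0.5–5 km cut-off scan and the cut-off maximising R² is selected;
   fixed-effects-only predictions calibrate every minute.
4. **Exposure assessment** — distribution summaries (mean, sd,
   2.5/25/50/75/97.5th percentiles, min, max), microenvironment time
   budgets, inhaled-dose apportionment (`dose_k = breathing_rate · Σ
   conc`), inverse-distance-weighted (power 2) home-address hourly series,
   and personal-vs-home comparison (Pearson r at minute and hour scales,
   P/O ratio distribution).
5. **Inference** — Wilcoxon/Kruskal–Wallis subgroup tests with Bonferroni
   post-hocs; the spatiotemporal linear mixed model

   ```
   PM2.5_calibrated ~ Landuse + IO * PM2.5_IDW + Season + Hour
                      + Age + Sex + Marital + Race + Edu + Income
                      + (1 | participant)
   ```

   with profile-likelihood CIs, Benjamini–Hochberg adjustment across the
   fixed effects, estimated marginal means per factor level, the
   indoor-stratum background slope (main effect + interaction),
   variance-components ICC, land-use Shannon entropy, and nested-model /
   leave-one-group-out sensitivity analyses.

Because raw personal monitoring data of this kind are not publicly
deposited, the package ships a first-class **synthetic study generator**
(`world_config()`, `simulate_study()`): a parcel landscape with building
footprints and a station network, ground-truth schedules hitting
configurable indoor (78%) and residential (67%) time targets, a seasonal +
diurnal + AR(1) ambient field with indoor infiltration, dinnertime cooking
and winter heating sources, GPS noise and gaps, and a known linear sensor
distortion — with complete per-minute ground truth, so every pipeline stage
can be validated by recovery.

## Worked example

```r
library(pmtrace)

cfg   <- world_config(seed = 42, n_participants = 4, n_days = 3,
                      stagger_days = 120)
study <- simulate_study(cfg)

clean  <- preprocess_stream(study$stream)
labels <- identify_context(clean, study$landscape, tz = cfg$tz)
context_accuracy(labels, study$truth)
#>       n microenv_pct indoor_pct joint_pct
#> 1 17280        100.0      100.0      99.9

scan <- scan_cutoffs(labels, clean, study$stations,
                     study$landscape$origin,
                     grid_km = c(0.5, 1, 2, 5), min_pairs = 30)
scan$fit
#> <pm_calibration> n = 31  R2 = 0.995  RMSE = 0.122 ug/m3
#>   fixed effects: (Intercept) = 7.7785, raw = 0.4884, rh = -0.0913, temp = 0.0973
#>   cut-off: 2 km

calibrated <- apply_calibration(scan$fit, clean)
minutes    <- labelled_minutes(labels, calibrated)
dose       <- apportion_dose(minutes)
dose$indoor_outdoor
#>   setting minutes mean_conc dose_ug time_fraction dose_prop
#> 1 indoor    13477      8.51   1376.         0.780     0.778
#> 2 outdoor    3803      8.61    393.         0.220     0.222
```

With 10-m GPS noise and 2% dropped fixes, 99.9% of minutes are labelled
with the correct microenvironment and indoor flag. The calibration slope
0.488 recovers the configured sensor distortion (true slope 0.5) from 31
opportunistic outdoor collocation hours, and indoor exposure carries 77.8%
of the inhaled dose while occupying 78.0% of time — dose shares track time
shares because concentrations differ only moderately between
microenvironments. `autoplot()` methods render the dose breakdown, the
calibration scatter and the model coefficients; `tidy()`/`glance()` return
the usual broom-style tables.

The whole chain, writing every product to disk, is one call:

```r
run_pipeline(study, "out/", infer = TRUE)
```

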