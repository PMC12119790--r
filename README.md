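# kinemed

Cycle-based kinematic analysis of the medication response in repetitive
hand movements.

## The problem

Clinical rating of parkinsonian bradykinesia from finger-tapping and
hand-opening tasks is subjective and coarse. Markerless video pose
estimation turns such a recording into a displacement time series — the
distance between two tracked landmarks sampled at the camera frame rate —
and that trace carries quantitative information about movement speed,
amplitude, rhythm, variability and the sequence effect (progressive
decrement across repetitions). `kinemed` is the analysis layer downstream
of the tracking: it is written for movement-disorders researchers who want
to estimate, feature by feature, how a dopaminergic challenge (medication
OFF vs ON) changes those kinematics across a cohort with repeated visits,
and to ask which *domains* of movement change together.

## What it computes

**Feature extraction.** A displacement trace is segmented into
valley–peak–valley movement cycles by prominence-filtered peak detection,
and summarised as 20 canonical features (`kinematic_features()`): means
and SDs of cycle amplitude, peak speed, RMS velocity, opening/closing
speed and cycle duration; movement frequency; duration range; CVs; and
three sequence-effect decay slopes (proportional change per cycle).

**Effect estimation.** Per feature and task, a linear mixed-effects model

```
feature ~ condition + age_at_visit + (1 | patient_id)
```

fitted by REML (OFF is the reference level), after masking values above
the per-task 99th percentile. The ON-vs-OFF coefficient β₁ is reported as

```
percentage change (%) = 100 · β₁ / baseline mean (OFF)
```

with Wald 95% CIs and p-values, Bonferroni-corrected across the canon
(0.05/20 = 0.0025).

**Sparse dimensions.** Per-visit ON−OFF difference scores are
standardized and decomposed by sparse PCA — minimising
½‖X − UV‖² + α‖V‖₁ with unit-norm scores and α = 1 — yielding components
with exact-zero loadings. The component count comes from the elbow of the
adjusted cumulative-variance curve, and the stability of each component
across tasks is measured by the Pearson correlation of its loading
vectors (features zero in both tasks excluded).

**Synthetic cohorts.** `simulate_signal()` / `simulate_cohort()` generate
ground-truthed quasi-periodic recordings with per-cycle jitter, linear
sequence-effect decays, patient-level heterogeneity, an age trend and a
multiplicative ON-state effect; `plant_factor_structure()` plants known
3-block factor structure for sparse-PCA validation. Every statistical
claim in the test suite is backed by these generators.

## Worked example

```r
library(kinemed)

## one recording ----------------------------------------------------------
sig <- simulate_signal(signal_spec(duration = 10), seed = 42)
sig
#> <movement_signal> finger_tapping: 573 samples @ 60 Hz (9.55 s), 18 cycles generated
round(extract_features(sig)[c("mean_amplitude", "mean_speed", "frequency",
                              "cv_cycle_duration", "amplitude_decay")], 4)
#>    mean_amplitude        mean_speed         frequency cv_cycle_duration
#>            0.9415            6.2551            1.8881            0.0587
#>   amplitude_decay
#>           -0.0092
```

The recording opens about 0.94 units per cycle at 1.89 cycles/s with a
peak speed of 6.26 units/s, shows 5.9% cycle-to-cycle timing variability
and loses ~0.9% of its amplitude per cycle — a mild sequence effect.

```r
## cohort-level medication effect -----------------------------------------
co <- simulate_cohort(
  cohort_spec(n_patients = 40, visits_mean = 2, visits_sd = 0, seed = 7),
  signal_spec(),                                   # OFF-state signal model
  condition_effect(amplitude_factor = 1.05, speed_factor = 1.11,
                   jitter_factor = 0.85, decay_factor = 0.95))
tab <- exclude_outliers(extract_feature_table(co))
eff <- medication_effects(tab, task = "finger_tapping")
head(as.data.frame(eff)[, c("feature", "pct_change", "p_value",
                            "bonferroni_significant")], 7)
#>               feature pct_change   p_value bonferroni_significant
#> 1      mean_amplitude       4.33  1.17e-64                   TRUE
#> 2          mean_speed      14.70 1.92e-231                   TRUE
#> 3   mean_rms_velocity      15.04 3.14e-248                   TRUE
#> 4  mean_opening_speed      14.87 8.38e-241                   TRUE
#> 5  mean_closing_speed      14.87 2.35e-250                   TRUE
#> 6 mean_cycle_duration      -9.54  0.00e+00                   TRUE
#> 7           frequency      10.47  0.00e+00                   TRUE
```

Speed-related features rise ~15% in the ON state while amplitude gains
only ~4% and cycle durations shorten — the selective speed response the
generator was configured to emulate. `report_effects()` across both tasks
then lists the features changing by more than 10% in each.

```r
## sparse dimensions on planted structure ---------------------------------
d <- planted_block_design()
pf <- plant_factor_structure(300, d$blocks, block_strengths = c(1.2, 0.9, 0.7),
                             noise_sd = 0.4, seed = 11)
fit <- fit_sparse_pca(standardize(pf$x), n_components = 8)
fit
#> <sparse_pca> 8 components, penalty 1, n = 300
#>   nonzero loadings: 7, 7, 6, 3, 5, 3, 5, 4
#>   adjusted EV fractions: 0.3, 0.282, 0.21, 0.0241, 0.0199, 0.016, 0.0152, 0.0139
#>   cumulative: 0.3, 0.582, 0.792, 0.816, 0.836, 0.852, 0.867, 0.881
select_n_components(fit)
#> [1] 3
top_loadings(fit, 1)
#>              feature  loading rank
#> 1     mean_amplitude 15.41137    1
#> 2         mean_speed 15.25168    2
#> 3  mean_rms_velocity 15.19770    3
#> 4 mean_opening_speed 15.04122    4
```

The three planted blocks come back as the top three sparse components
(supports of size 7/7/6), the variance curve elbows at 3, and the leading
component is defined by the speed features — the radar-plot view of a
"movement speed" domain. `loading_stability()` compares such components
across tasks.

`run_pipeline(run_config(seed = 1), out_dir = "out")` executes the whole
chain — simulate (or ingest a feature CSV), extract, mask outliers, fit
per-feature models per task, difference, standardize, sparse PCA,
stability — and writes CSV/JSON artifacts with a manifest; identical
configuration and seed reproduce byte-identical outputs.

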