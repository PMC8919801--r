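# tapkin

Kinematic analysis of finger-tapping assessments from markerless
hand-landmark recordings.

Finger tapping — touching the index fingertip to the thumb as fast and
fully as possible — is a standard clinical probe of upper-limb motor
function. Ataxia disturbs its rate and rhythm (slower, more variable
taps); parkinsonism shows amplitude decrement and slowing. Video pose
trackers reduce the task to per-frame coordinates of three landmarks
(index tip, thumb tip, wrist); the index–thumb distance
`TS(t) = ||p_index(t) − p_thumb(t)||` is then a quasi-periodic signal
whose shape carries the phenotype.

`tapkin` implements the full chain for clinicians and methods
researchers working with such recordings:

* **Preprocessing** — leave-one-out cubic outlier screening, cubic gap
  interpolation (≤ 0.5 s), resampling to 30 Hz, zero-phase 10 Hz FIR
  low-pass, z-scoring, derivatives to jerk.
* **Events & features** — prominence-based peak/trough detection; five
  feature families (TS, Pk, Th, PkTh, Th-Th) built from 11 summary
  measures per series, event slopes, and a per-cycle quadratic model
  `amp ~ c + b·τ + a·τ²` on normalised cycle time whose curvature
  coefficient `a` is the key rhythm feature.
* **Models** — per-family PCA (2 PCs × 5 families = 10 inputs),
  L1/L2-penalised logistic classification and ridge severity regression
  under subject-grouped, class-stratified 10-fold cross-validation with
  inner-loop regularisation tuning; feature contributions as
  (model coefficient) × (PCA loading); diagnostics (probability–age /
  –severity correlations, Welch t tables).
* **Synthetic cohorts** — a generator emulating ataxic, parkinsonian and
  control tapping (group-dependent rate, period/amplitude variability,
  amplitude decrement, tracking noise, dropouts, spikes) with severity
  labels tied monotonically to the generative parameters, so the whole
  pipeline is testable without clinical data.

## Worked example

```r
library(tapkin)

# a small two-group cohort: 30 ataxia + 30 control recordings per hand
cohort <- generate_cohort(cohort_spec(n_ataxia = 30, n_parkinsonism = 0,
                                      n_control = 30, seed = 7))

# preprocess every recording and extract the canonical feature inventory
cf <- cohort_features(cohort, "canonical")
cs <- contrast_subset(cf$sessions, "ataxia_vs_control")

fit <- classify_groups(cf$features[cs$idx, ], cs$labels,
                       cf$sessions$subject_id[cs$idx],
                       positive = cs$positive, k = 5, seed = 1,
                       n_boot = 100)
fit
#> <model_report> classification (positive = ataxia, L1 penalty)
#>   AUC 1.000 (1.000-1.000)  sens 1.000  spec 1.000  [n = 58]

sev <- regress_severity(cf$features, cf$sessions,
                        cf$sessions$subject_id,
                        target = "severity_dominant", k = 5, seed = 1,
                        n_boot = 100)
sev
#> <model_report> regression (target = severity_dominant)
#>   r 0.970  r2 0.941  [n = 58]

head(feature_contributions(fit), 3)
#>              feature family contribution rank  top
#> 1 nd.ts.acc.abs_mean     TS   -0.2233449    1 TRUE
#> 2      nd.ts.acc.std     TS   -0.2232365    2 TRUE
#> 3      nd.ts.vel.std     TS   -0.2229159    3 TRUE
```

The default presets separate strongly, so AUC saturates at this size;
the out-of-fold severity correlation (`r = 0.97`) says the ridge model
recovers the generative severity ordering almost perfectly, and the
contribution table says time-series velocity/acceleration dispersion
carries most of the discrimination — consistent with what the features
were designed to measure. Two of the sixty sessions fail quality control
(simulated tracking gaps longer than the interpolable 0.5 s) and are
logged in `cf$failures` rather than analysed.

A feature table's manifest records the inventory arithmetic; the
`"paper-total"` profile emits exactly 256 features per two-hand
assessment:

```r
attr(cohort_features(cohort, "paper-total")$features, "manifest")$total
#> [1] 256
```

A thin command-line front end with verbs `synth`, `validate`,
`preprocess`, `features`, `model`, `run` is installed at
`inst/scripts/tapkin.R`.

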