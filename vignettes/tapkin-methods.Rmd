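---
title: "Finger-tapping kinematics with tapkin: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finger-tapping kinematics with tapkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tapkin)
```

## The problem

Finger tapping — repeatedly touching the index fingertip to the thumb as
fast and fully as possible — is a standard bedside probe of upper-limb
motor function. Cerebellar ataxia disturbs the *rate* and *rhythm* of the
movement (slower taps, more variable cycle periods and amplitudes);
parkinsonism produces progressive *amplitude decrement* and slowing.
Markerless pose trackers turn a video of the task into per-frame
coordinates of a few hand landmarks, and the Euclidean distance between
the index fingertip and the thumb tip becomes a quasi-periodic
one-dimensional signal whose shape carries the phenotype.

`tapkin` implements the full analysis chain from those landmark time
series to group classification and severity regression, plus a synthetic
cohort generator so the chain can be exercised and validated end to end
without clinical data.

## Signal conditioning

`preprocess_recording()` applies, in order:

1. **Trim** to the annotated task segment (or, without an annotation, the
   longest window whose rolling 1 s amplitude range exceeds 25% of the
   global range).
2. **Distance**: per-frame index-thumb Euclidean distance; frames with a
   missing landmark or confidence below 0.1 become missing.
3. **Outlier screening**: each sample is re-estimated by the cubic through
   its four nearest valid neighbours with the sample held out; the
   absolute difference is its *deviance*. Samples are masked worst-first
   whenever deviance exceeds 6x the series' median deviance (re-estimating
   neighbours after each removal so a single spike cannot drag its
   neighbours over the threshold). An absolute floor of
   `sqrt(.Machine$double.eps)` times the series range prevents pure
   floating-point residue from being flagged on analytically smooth
   input. The threshold unit is robust (median deviance), since the paper
   trail for this kind of QC never fixes an absolute scale.
4. **Gap interpolation**: interior missing runs up to 0.5 s are filled by
   the local cubic through the four nearest valid samples (which is exact
   for cubic trajectories); longer gaps are unrecoverable and fail the
   recording; leading/trailing missing runs are dropped, never invented.
5. **Resampling**: 60 Hz recordings are anti-alias filtered (zero-phase
   FIR) and decimated to 30 Hz.
6. **Low-pass**: linear-phase windowed FIR, cutoff 10 Hz, order ~2 s of
   samples, taps renormalised for exact unit DC gain, applied
   forward-backward with mirror padding (the plain forward-backward pass
   otherwise leaves edge transients).
7. **Z-score**: exact zero mean and unit variance, removing the amplitude
   scale set by the hand-camera distance.
8. **Derivatives**: velocity, acceleration and jerk by central finite
   differences scaled by the sampling rate (one-sided at the edges).

QC order matters: screening and gap filling act on raw pixel distances so
that spikes cannot corrupt the z-score's scale estimate; normalisation is
last.

A note on the filter and "exact" tests: the synthetic waveform is a chain
of parabolic cycles, which has harmonics above 10 Hz at the ~1% level.
Any faithful 10 Hz low-pass therefore perturbs it; exact-recovery
assertions in the test suite disable the filter
(`preprocess_config(lowpass_hz = NULL)`), while the filter itself is
tested on its own terms (unit DC gain, <2% passband ripple at 2 Hz, >90%
attenuation at 13 Hz). Likewise, the parabola has a slope discontinuity
at each trough whose leave-one-out cubic deviance (~21 px at typical
amplitudes) legitimately exceeds the robust threshold, so the default
chain rounds off trough vertices on synthetic input; real tapping traces
are smooth at finger contact and do not trigger this.

## Events and the five feature families

`detect_events()` finds local maxima with topographic prominence >= 0.5
z-units and >= 0.15 s separation (plateaus from sampling ties collapse to
their midpoint), then takes the minimum between consecutive peaks as the
trough, giving a strictly alternating peak/trough sequence. The
prominence and separation defaults are package choices — the upstream
literature names the detection idea but no parameters — set well below
the amplitude (~2 z-units peak-to-trough) and period (>= 0.25 s) of any
plausible tapping signal.

`extract_features()` then computes, per hand:

| Family | Content | Count (canonical) |
|--------|---------|-------|
| TS | 11 summary measures of the amplitude and each of its 3 derivatives, + spectral peak frequency | 44 (+1) |
| Pk | 11 measures of peak amplitudes and their 1st-3rd event-time derivatives, + OLS slope | 45 |
| Th | same for troughs | 45 |
| PkTh | mean/SD/median of peak-to-next-trough time and amplitude drop | 6 |
| Th-Th | mean/SD/median of the per-cycle quadratic curvature coefficient | 3 |

The 11 summary measures are mean, absolute mean, max, min, SD, median,
10th/90th percentile (linear interpolation), range, IQR, and Shannon
entropy in nats of the 16-bin equal-width histogram over `[min, max]`
(defined as 0 for a constant sequence — the bin count and nats are
package choices, as the upstream description does not pin them down).
Event-series derivatives are finite differences with respect to *event
time*, not event index, because periods are irregular and the features
are kinematic. The spectral peak is the argmax of a Welch power spectral
density (hann-windowed 4 s segments, 50% overlap) searched in 0.5-10 Hz.

Each trough-to-trough cycle is parameterised by least squares as
`amplitude ~ c + b*tau + a*tau^2` on normalised cycle time `tau` in
`[0, 1]`; the curvature coefficient `a` is the featurised quantity. The
synthetic generator's cycles are exactly quadratic in `tau`, which gives
these fits an analytic test surface: on clean input the residuals vanish
and a cycle sampled from `4*tau*(1-tau)` recovers `(a, b, c) =
(-4, 4, 0)` to 1e-9.

### Inventory arithmetic and the `paper-total` profile

The canonical profile emits 144 features per hand (143 + the documented
spectral-peak extension). The literature this design follows states a
256-dimensional inventory without spelling out its decomposition;
`feature_profile("paper-total")` is this package's reconciliation.
Enumerating the documented switches (hands, spectral peak on/off,
event-family derivative depth, curvature-only vs all three quadratic
coefficients) shows exactly one combination reaching 256: both hands,
spectral peak on, event derivatives to 2nd order (3 series x 11 + slope
= 34 per event family), and all three quadratic coefficients summarised
(9 Th-Th features): 2 x (45 + 34 + 34 + 6 + 9) = 256. Every feature
table carries a machine-readable manifest with the per-family counts so
this arithmetic is checkable rather than assumed.

## Dimension reduction and models

`fit_family_pca()` standardises each feature and decomposes each family
independently, keeping 2 components per family (10 model inputs in
total). Signs are fixed by making each component's largest-magnitude
loading positive; numerically constant columns (e.g. the identically-zero
mean of a z-scored amplitude) are dropped.

`classify_groups()` fits penalised logistic regression (L1 default — it
zeroes uninformative components and gives sparse contribution reports;
L2 available) with subject-grouped 10-fold cross validation: all
recordings of a subject share a fold, so repeat visits can never
straddle train and test. The regularisation strength is tuned per outer
fold by a grouped inner 10-fold CV over a 13-point log-spaced grid
(1e-3 to 1e3), minimising validation log-loss. AUC, sensitivity and
specificity are computed on the pooled out-of-fold probabilities at the
0.5 operating point, with subject-level percentile-bootstrap 95%
intervals (1000 resamples).

Two design points deserve explanation:

* **PCA scope.** Whether standardisation + PCA should be fit once
  globally or inside every training fold is genuinely open in this kind
  of pipeline. The default is per-fold (leakage-safe); `pca_scope =
  "global"` reproduces the simpler one-shot procedure. The per-fold
  default is also what the no-leakage test asserts: perturbing a test
  row never moves the predictions of other rows in its fold.
* **Stratified grouped folds.** With plain grouped folds, the class mix
  drifts from fold to fold, and pooled out-of-fold AUC is then biased
  *below* 0.5 under label permutation — even an intercept-only model
  anti-predicts, because a test fold rich in cases leaves a case-poor
  training set. Measured on the default synthetic contrast this bias
  reaches mean AUC ~0.37. Classification folds are therefore stratified
  by class within the grouped assignment (the behaviour of the standard
  grouped-stratified splitters in mainstream ML toolkits), which
  restores a calibrated null (mean permuted AUC ~0.49) without touching
  the subject-grouping guarantee. Regression folds are unstratified.

`regress_severity()` uses ridge regression (the quadratic penalty suits
a continuous target driven by many small effects) with the same grouped
CV and tuning; performance is the Pearson `r` between pooled out-of-fold
predictions and the truth, and the reported `r2` is defined as `r^2`
(explained variance in the correlation sense, so printed pairs are
always self-consistent).

`feature_contributions()` maps a fitted PC-space model back to the
original features: contribution(feature) = sum over its family's
components of coefficient x loading. This is an exact re-expression of
the linear model on standardised features (asserted against a
brute-force expansion), and L1-zeroed components contribute exactly
nothing. The top 2% by magnitude are flagged for plotting.

`common_arm_score()` harmonises clinical scales onto `[0, 1]`: ataxia
arm score / 4, parkinsonism arm composite / 12 (the divisor is
configurable to 24, since published summary tables are consistent with
either reading), controls exactly 0.

## The synthetic cohort generator

`generate_tapping_recording()` builds cycle chains with period
`T_k = (1/rate) * max(0.2, 1 + period_cv * e_k)` and peak amplitude
`A_k = base * (1 + slope * t_k) * max(0.1, 1 + amp_cv * n_k)`
(standard-normal `e_k`, `n_k`; the truncation floors keep periods and
amplitudes positive at high CV). The within-cycle waveform is the
parabola `A_k * 4 * tau * (1 - tau)` — chosen over a half-sine so the
trough-to-trough quadratic model is *exact* on clean data. Landmarks are
placed in a fixed 960x540 scene and corrupted with i.i.d. Gaussian
jitter, geometric-length dropout gaps, and spike outliers on the index
fingertip.

Group presets encode reported phenotype directions with invented,
configurable magnitudes (no quantitative magnitudes exist to calibrate
against):

| Group | rate (Hz) | period CV | amp CV | amp slope (1/s) |
|-------|-----------|-----------|--------|------------------|
| control | 3.0 | 0.05 | 0.08 | 0 |
| ataxia | 1.8 | 0.25 | 0.25 | 0 |
| parkinsonism | 2.8 | 0.10 | 0.12 | -0.03 |

Noise defaults (all presets): jitter SD 2 px, dropout probability
0.01/frame with mean gap 0.1 s, spike probability 0.005/frame at 40 px —
plausible magnitudes for a consumer camera with a well-trained tracker.
About 2-5% of generated recordings draw a dropout gap longer than the
0.5 s interpolation cap and are dropped by QC with a logged failure;
this is deliberate realism, not an error.

`generate_cohort()` draws subject-level parameters around the presets
(rate SD 0.3 Hz; log-normal spread with relative SD 0.3 on both CVs;
slope SD 0.01/s), gives the nondominant hand 10% higher variability,
assigns 20% of recordings as second visits of existing subjects, draws
ages from per-group truncated normals (49 +/- 22, 67 +/- 8, 30 +/- 20
years), and derives all clinical labels from the generative severity.

`severity_from_params()` is the deterministic monotone map
`clip01(0.6 * period_cv + 0.3 * amp_cv + 0.45 * rate_deficit)` with
`rate_deficit = max(0, (3 - rate)/3)`, and exactly 0 for controls. The
coefficients were chosen once so the group means land near typical
published common-arm severities (ataxia ~0.4, parkinsonism ~0.13)
without saturating the clip — saturation would flatten the
severity-feature relationship the regression is supposed to recover.
Arm scores are the severity mapped back to the native scales (0-4 in
0.5 steps; 0-12 integer composite), totals add small Gaussian noise
before rounding.

### What the generator does and does not emulate

It reproduces: group-dependent rate, rhythm and amplitude variability,
amplitude decrement, tracking jitter, dropouts, spikes, repeat visits,
age structure, severity tied to the generative parameters. It does not
reproduce: hand drift toward/away from the camera (depth effects),
within-trial fatigue beyond the linear amplitude slope, tremor
superimposed on the tap cycle, smooth deceleration into finger contact
(its cycles meet at a kink), or realistic correlations between age and
severity. Passing tests therefore demonstrate that the pipeline measures
what it claims on signals with this structure — not that the printed
clinical performance numbers would be reproduced on real cohorts, whose
data are not available.

## Problem sizes and determinism

The shipped validation suite runs the full chain at deliberately chosen
sizes: 100 + 100 recordings per classification cohort over 20 seeds,
100 label permutations for the null, 75 + 75 for severity recovery over
20 seeds, 100 five-vs-five cohort pairs for the directional checks, and
1000 random rosters for fold integrity. These sizes give stable Monte
Carlo estimates (binomial SE < 3% on the directional fractions) while
keeping a laptop run in minutes. All randomness flows from explicit
seeds; identical configs reproduce byte-identical reports, and seeds
derived internally stay below 2^31.

## Known limitations

* The auto-trim heuristic is a fallback; segment annotations are better.
* Sensitivity/specificity use a fixed 0.5 operating point (none is
  prescribed upstream); threshold-free comparisons should rely on AUC.
* The severity map is linear in its axes; real clinical scales are
  ordinal and nonlinearly spaced.
* `r2 = r^2` is a correlation-based quantity, not an out-of-sample
  coefficient of determination; it cannot be negative and will flatter
  a biased-but-correlated predictor.
* Single-spike recovery is exact, but bursts of adjacent spikes longer
  than the interpolation cap fail the recording rather than being
  repaired.
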