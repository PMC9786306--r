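---
title: "Continuous fatigue monitoring from forearm wearables: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous fatigue monitoring from forearm wearables: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(aftmon)
```

## The problem and the statistic

Physically demanding trades such as scaffold building expose workers to
sustained aerobic workloads. Occupational guidelines hold that average
oxygen uptake over a workday should not exceed one third of the
*activity-specific maximum aerobic capacity* (MAC). `aftmon` implements a
monitoring pipeline built around the **aerobic fatigue threshold**

$$\mathrm{AFT}_t \;=\; \frac{\dot VO_{2,t}\;[\mathrm{L/min}]}
{\mathrm{MAC}(\text{activity}_t)\;[\mathrm{L/min}]},$$

the ratio of a worker's instantaneous oxygen uptake to the MAC of the
activity being performed at that second. Because both the numerator
(predicted from forearm EMG and IMU signals) and the denominator (an
activity-specific constant, looked up after recognizing the activity) are
activity-dependent, the statistic adapts to task switches that occur every
few minutes on a real site. The companion comparator is the percent
heart-rate reserve,
$\%\mathrm{HRR}_t = (HR_t - HR_{rest}) / (HR_{max} - HR_{rest})$ with
$HR_{max} = 220 - \text{age}$.

One unit decision deserves emphasis because no published source spells it
out: wearable metabolic analyzers report oxygen uptake per unit body mass
(mL/kg/min) while MAC tables are absolute (L/min). `compute_aft()`
therefore converts the numerator through body mass,
$\dot VO_2\,[\mathrm{L/min}] = \dot VO_2\,[\mathrm{mL/kg/min}]\times
\text{mass}\,[\mathrm{kg}]/1000$, before dividing. This is the single most
consequential reconciliation in the package and every AFT number it prints
depends on it.

The MAC table ships with four categories (Walking 2.946, Carrying 2.552,
Lifting 2.816, Combined 2.304 L/min) and a fixed mapping from the fourteen
scaffold-building activity codes to categories; hammering, wrenching and
dragging share the Combined value, a known coarseness of the source
constants rather than a modeling choice of ours.

Subjective fatigue is handled on the 0–10 rating-of-fatigue (ROF) scale,
collapsed to five levels (None, Low, Moderate, High, Very High) with
boundaries after ratings 0, 2, 5 and 7. The generator inverts this
mapping through empirical per-level AFT means (22.03%, 28.91%, 36.00%,
43.63%): band cut points sit at the midpoints of consecutive means
(0.11015, 0.2547, 0.32455, 0.39815 as fractions), and each band reports
its range's lower-median rating (0, 1, 4, 6, 9). Even-sized rating ranges
have no middle integer; taking the lower median keeps
`rof_to_level(rof_label_from_aft(a)$rating)` an identity on levels.

## The pipeline

`run_pipeline()` executes six stages: (i) data acquisition — here the
synthetic generator; (ii) multi-rate synchronization into per-second
windows; (iii) feature extraction and selection; (iv) sequence models for
activity recognition and oxygen-uptake regression with leave-one-subject-
out (LOSO) cross-validation; (v) continuous AFT/%HRR computation against
the MAC table; (vi) fatigue-level classification and agreement testing.
Each stage is exposed as an ordinary function (and a CLI subcommand in
`inst/cli/aftmon.R`), and every reported number is recomputable from the
persisted intermediates.

### Synchronization and features

The device suite is heterogeneous: 8-channel surface EMG at 200 Hz,
9-axis IMU at 50 Hz, oxygen uptake and heart rate at 1 Hz. Windows are
half-open seconds $[t, t+1)$, 0-based; a window is kept only if both
high-rate blocks are complete, so a session contributes
`floor(common duration)` windows. Sparse fatigue ratings attach to the
most recent rating at or before a window's start.

Each window yields **289 features: 17 statistics × 17 channels**. The
statistic list (documented in `feature_names()`) covers the standard
surface-EMG time-domain set — mean absolute value, RMS, waveform length,
zero crossings, slope-sign changes, energy — plus distributional moments,
order statistics and a dominant-frequency bin from the periodogram. The
published description of the upstream system states the count and the
channel inventory but never enumerates the features; 17 × 17 is the only
decomposition consistent with both, and the particular list is this
package's fixed, documented choice. Two selection procedures follow the
published protocol: the activity model keeps the top-k features by one-way
ANOVA F (k = 100 at full protocol scale), then standardizes (z-score);
the oxygen model keeps features with |Pearson r| > 0.1 **and** mutual
information > 0.1 against VO2 (16-bin equal-frequency plug-in estimator —
the source names no estimator), then min-max normalizes. "Greater than
0.1" is read as a conjunction; both thresholds are config-overridable.
Selection and scaling are always re-fit inside each CV fold on training
rows only; the source does not state this, but anything else leaks
held-out information.

### Sequence models

Both tasks use the same architecture: two stacked bidirectional LSTM
layers, dropout after each block, a relu dense layer, and a softmax (14
classes, cross-entropy) or linear (MSE) head. No deep-learning framework
is part of this package's stack; the BiLSTM — forward pass, backpropagation
through time, Adam — is implemented in compiled C++ (`src/bilstm.cpp`) and
verified against finite-difference gradients in the test suite. Inputs are
sliding windows of L seconds ending at the predicted second, left-padded
by repeating the first row so every second of a session receives a
prediction; training may subsample window starts with a stride, evaluation
windows may too, but deployment-style monitoring always predicts at
stride 1. Training is seeded and single-threaded, hence reproducible.

Defaults mirror the published architecture scale (hidden 64/32, dropout
0.3, ≤ 50 epochs with early stopping on a 10% split); the *reference
study* (`study_config()`) uses a desk-scale variant — L = 30, stride 20,
hidden 16/8, 6 epochs for the classifier and ≤ 14 with early stopping for
the regressor, top-30 ANOVA features — chosen so a full 10-fold LOSO study
of both models runs in minutes on one CPU while remaining comfortably
above the package's acceptance bars (LOSO activity accuracy ≥ 0.90,
per-second VO2 R² ≥ 0.70 measured on every fifth second of the held-out
subject). Doubling these sizes improves the metrics only marginally on the
synthetic data; the bottleneck is between-subject variability, not
capacity.

### Fatigue classification

Per-segment feature vectors take {mean, min, max, sd} of each of AFT, HR
and %HRR over a segment (an activity bout, or a 1-/2-minute tumbling
window) — twelve features, min-max normalized over the training table;
held-out tables reuse the training scaler. Ten classical classifiers (RF,
DT, NB, LDA, QDA, SVM, AdaBoost, logistic regression, KNN, MLP) are
compared under stratified 10-fold CV with library-default
hyperparameters and a fixed seed; macro-averaged precision/recall/F1
accompany accuracy, and the best model per feature subset is chosen by
accuracy with an F1 tie-break. AdaBoost is a short in-package SAMME
implementation over shallow `rpart` trees, since no boosting package of
that family is part of the stack. Agreement between actual and predicted
levels uses the Pearson chi-squared statistic on the contingency table of
levels present in the data (no continuity correction), so four observed
levels give df = 9.

## The synthetic-data generator

No participant data accompanies the published study, so the generator is
a first-class module that emulates the statistical structure the pipeline
assumes; its defaults are the study conditions.

* **Cohort and schedules.** Ten workers (age 27 ± 1.7 y, mass
  76.7 ± 8.25 kg, height 171.7 ± 4.13 cm, resting HR 70 ± 8 bpm), each
  performing all fourteen activities for five minutes in randomized order,
  with a fatigue rating every five minutes. The evaluation worker (29 y,
  75 kg, 168 cm, resting HR 96) follows the bundled ~85-minute schedule —
  fifteen bouts whose durations sum to 84.82 min, ladder climbing cut to
  1.40 min by exhaustion — rating fatigue every minute. Streams truncate
  to whole seconds (the printed sample count of the source session differs
  from its summed durations by one second; we truncate rather than chase
  that discrepancy).
* **Oxygen kinetics.** VO2 follows piecewise first-order on-kinetics
  toward each activity's steady-state target with τ = 35 s — a typical
  on-kinetics constant; the source states only that oxygen uptake is
  activity-dependent. Measurement noise is N(0, 0.5²) mL/kg/min, floored
  at zero.
* **Calibration.** Steady-state targets are set, per activity, so that a
  75-kg reference worker's per-activity AFT means span the five level
  bands — ladder climbing highest (≈ 0.46), hammering lowest (≈ 0.18),
  and the frame/baseboard/ladder tasks above the 33% exposure limit.
  These are calibration constants of the generator, not physiological
  claims.
* **Heart rate.** Linear in noise-free VO2 (5 bpm per mL/kg/min) with
  AR(1) noise (ρ = 0.9, σ = 2 bpm), clipped to [resting, 220 − age].
* **EMG.** Band-limited (20–95 Hz) unit-variance noise scaled per second
  by an activity × channel activation pattern in [0, 1]. The nominal
  20–150 Hz surface-EMG band cannot be represented at the device's own
  200 Hz sampling rate (Nyquist 100 Hz), so the upper edge is 95 Hz.
  Activation patterns come from a discrete harmonic basis — near-orthogonal
  across activities so the streams carry activity identity, with overall
  level scaling in workload so they also carry intensity.
* **IMU.** Gravity offset plus an activity-specific sinusoid (dominant
  frequency 0.6–3.4 Hz, amplitude patterns analogous to EMG) plus noise;
  orientation channels are slow AR(1) drifts around activity-specific
  levels, with no quaternion algebra — the pipeline consumes only channel
  statistics.
* **Between-worker variability.** Every simulated worker — including the
  evaluation worker — receives a personal catalog perturbation: VO2
  targets × N(1, 0.05²) per activity (fitness) and EMG channel gains
  × N(1, 0.1²) (electrode placement). Without this the held-out worker
  would be unrealistically easy and held-out prediction error would
  vanish.
* **Ratings.** A rating emitted at time $t$ bands the mean AFT over the
  trailing 300 s (`rof_memory_s`), regardless of how often ratings are
  collected: perceived fatigue integrates the last few minutes of work,
  not merely the interval since the previous question. This matters for
  the window-size comparison below.

What the generator does **not** emulate: muscle-fatigue spectral drift,
thermoregulation, realistic gait biomechanics, device dropouts or clock
drift. Passing tests therefore demonstrate that the pipeline's machinery
— synchronization, features, selection, sequence models, AFT arithmetic,
classification — recovers known structure under the stated noise model;
they do not certify accuracy on real site data, and the published
real-data accuracies are explicitly out of reach without the undeposited
recordings.

## Numerical and design notes

* Tumbling averaging windows anchor at t = 0 and never overlap; a
  trailing partial window is emitted with its true length and flagged.
* The 33% exposure flag is a strict exceedance (`aft > 0.33`), matching
  the "cannot exceed" phrasing of the guideline.
* ANOVA-F ties break by column order; constant columns score 0 and a
  column constant within every class but varying between classes scores
  Inf, ranking first — both are tested.
* Zero-variance columns are excluded from correlation/MI selection, and
  zero-range/zero-sd columns map to 0 under scaling, each with a logged
  note.
* The dominant-frequency statistic excludes DC and resolves ties toward
  the lowest bin; an all-zero channel reports 0 Hz.
* Chi-squared tables drop empty rows/columns (a zero margin would make
  the Pearson statistic undefined); degenerate 1 × c tables are an error,
  reported as NA by the pipeline rather than aborting a run.
* QDA can fail on a fold when a within-class covariance is singular
  (likely with four highly correlated AFT features and ~30 rows per
  class); the comparison reports NA for that model instead of failing.
* The published input shape "[100, 100, 14]" for the activity model is
  internally inconsistent with its stated sample and feature counts and is
  treated as a typo; sequences here are [N, L, features].

## The reference study and what it reports

`study_config(seed)` fixes the desk-scale study; `run_pipeline()` returns
(and `scripts/acceptance.R` re-computes from scratch and writes as JSON)
the headline quantities: LOSO activity accuracy and macro-F1, pooled
per-second LOSO VO2 R² and RMSE, decision-tree 10-fold CV accuracy on
AFT-only / HR-only / %HRR-only fatigue features (140 samples = 10 workers
× 14 activities), per-second and windowed actual-vs-predicted AFT
regressions on the unseen session, per-scheme fatigue accuracies, and the
chi-squared agreement test. On synthetic data the qualitative pattern of
the published study reproduces: AFT features dominate HR and %HRR
features, two-minute windows beat one-minute windows (the trailing-window
rating memory plus prediction-error smoothing is exactly why), and
actual-vs-predicted fatigue levels are strongly associated.

The window-size comparison in the acceptance suite uses 20 seeded
replicate evaluation sessions and compares scheme medians; the
per-replicate sessions run through the full predicted-AFT path (activity
recognition → VO2 regression → AFT → features → classifier), not through
actual AFT, because the advantage of longer windows comes from averaging
prediction error — with noise-free AFT the shorter window is trivially
better and the comparison would be meaningless.

## Limitations

Calibration targets the level bands, so absolute VO2 magnitudes for some
activities sit below field tables for comparable work; the generator
optimizes band structure, not metabolic realism. The MAC constants are
treated as known rather than estimated from submaximal tests. Sequence
models see only 30 s of history in the reference study, less than one
kinetics time constant, which bounds accuracy during on-transients. All
error rates quoted anywhere in this package are measured on synthetic
data.
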