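---
title: "Multimodal hand-gesture classification: model, pipeline and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal hand-gesture classification: model, pipeline and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmgesture)
```

## The problem

Surface electromyography (EMG) based gesture recognition degrades badly in
users with motor impairment: muscle activation is weak, inconsistent, and
hyposensitive to low-strength gestures. Force myography (FMG) — the
contact-pressure profile a wristband of barometric sensors reads from
tendon and muscle deformation — responds to exactly those low-strength
movements, and a wrist-mounted inertial unit (IMU) adds gross kinematics.
This package implements a complete fusion pipeline over that sensor set:
six EMG channels at 1926 Hz, eight FMG channels and twelve IMU channels
(3-axis acceleration, angular rate, magnetic field and Euler angles) at
36 Hz, classifying twelve rehabilitation-relevant gestures — eleven
hand/wrist/forearm movements drawn from the Fugl-Meyer Assessment plus a
rest class (`movement_labels()`).

## Signal model of the synthetic generator

No clinical recordings ship with the package; a seeded generator
(`synth_config()`, `generate_trial()`) emulates the training protocol so
every downstream stage is testable. Each trial presents the 12 gestures in
a fixed order, 6 s per movement with 4 s rest gaps (116 s per trial, five
trials per subject), with a trigger at each onset.

Per movement block $c$ with raised-cosine envelope $e_c(t)$ (0.25 s ramps,
imitating the activation bursts at movement transitions that the trimming
rule exists to remove):

* **EMG**, channel $j$: $g\,(\phi + \gamma A_{cj} e_c(t))\, n_j(t)$ where
  $n_j$ is unit-variance Gaussian noise band-limited to 20–450 Hz — the
  standard amplitude-modulated surrogate for surface EMG — $g = 0.8$ mV,
  $\phi = 0.02$ a resting noise floor, and $A \in [0,1]^{12\times 6}$ the
  activation signatures. EMG is stored in volts so the ZC/SSC amplitude
  threshold $\epsilon = 4\times10^{-6}$ V applies in native units.
* **FMG**, channel $k$: baseline (50 u) $+\ \gamma F_{ck} e_c(t)$ + a slow
  sinusoidal drift (5 % of baseline, 40 s period — the reason per-trial
  normalization exists) + white noise ($\sigma = 1$ u).
* **IMU**, channel $m$: a static pose baseline $+\ \gamma M_{cm} e_c(t)$ +
  white noise ($\sigma = 0.3$).

The signature matrices are fixed defaults engineered for **designed
complementarity**: cylinder and spherical grip (CG/SG) share identical EMG
and IMU rows and differ only in FMG; mass flexion and hook grasp (MF/HG)
differ only in EMG; thumb adduction and opposition (TA/O) are deliberately
close in every modality; finger movements carry near-noise IMU offsets
(the IMU sits on the wrist) while wrist/forearm movements carry large
ones. Single-modality models therefore confuse the designed pairs while
the fused model resolves them — the qualitative behaviour the fusion
claim rests on. An `impairment_profile()` attenuates all signatures by
$\gamma \in (0,1]$ and can blend confusable-pair signatures, a coarse
stand-in for heterogeneous motor impairment.

What the generator does **not** emulate: motor-unit firing statistics,
electrode lift-off and sweat artefacts, IMU orientation kinematics,
cross-channel EMG crosstalk, or session-to-session electrode shift.
Passing tests on synthetic cohorts therefore demonstrate correctness of
the pipeline and the designed modality interplay, not clinical-grade
accuracy: noise levels are free parameters of the generator, chosen once
as plausible for the hardware class, not claims about any device.

## From raw streams to the 68-dimensional feature vector

Movements are segmented by their triggers
(`segment_by_triggers()`; ranges are 0-based half-open sample intervals,
`[round(onset * rate), round((onset+6) * rate))` on each stream's own
clock). The first 2 s and last 0.5 s of each movement are trimmed
(`trim_rule()`): transition bursts inflate EMG amplitude and impaired
users are slow to initiate, so only the steady 3.5 s core is kept.

EMG is windowed with 222 ms windows stepped by 55.6 ms; FMG/IMU with
disjoint 55.6 ms windows. The derived integer counts are frozen in
`windowing_config()`: 428 and 107 samples at 1926 Hz, 2 samples at 36 Hz
(round-half-up of 427.57, 107.09, 2.0016). A 3.5 s trimmed movement yields
exactly $\lfloor(6741-428)/107\rfloor + 1 = 60$ frames. Each EMG frame is
paired with the **latest complete disjoint low-rate window ending no later
than the EMG window's end time** — a causal synchronization rule that
never reads future low-rate samples.

Per frame: 8 features per EMG channel — MAV, waveform length, threshold
zero crossings, threshold slope-sign changes, and 4 Burg AR coefficients —
plus the MAV of each FMG and IMU channel: $6\times8 + 8 + 12 = 68$
features in a frozen order (`feature_names()`). Conventions that the
field leaves ambiguous are config-isolated in `feature_config()`:

* ZC counts sign changes with $|x_i - x_{i+1}| \ge \epsilon$ on the
  crossing pair; SSC requires the larger adjacent difference of a local
  extremum to reach $\epsilon$. Both are homogeneous: scaling the signal
  and $\epsilon$ together leaves the counts unchanged (property-tested).
* AR(4) uses the Burg recursion (stable on 428-sample windows),
  implemented vectorized over all of a trial's windows and tested to
  machine precision against `stats::ar.burg`; a least-squares fallback is
  selectable. Zero-variance channels yield zero coefficients and flag the
  frame rather than erroring mid-pipeline.
* FMG samples outside the sensor's measuring range (session metadata,
  default 0–115 u) invalidate every frame whose low-rate window touches
  them (`drop_invalid_fmg()`); invalid frames are excluded from training,
  testing and voting, and the raw streams are never resampled.

Features are normalized per trial to zero mean and unit variance
(`zscore_by_trial()`), with the applied statistics stored for exact
inversion; constant columns collapse to zero with a logged message.

## The classifier

The centerpiece is linear discriminant analysis implemented directly from
its discriminant function,
$$\delta_k(x) = x^\top \Sigma^{-1}\mu_k - \tfrac12 \mu_k^\top
\Sigma^{-1}\mu_k + \log\pi_k,$$
with $\mu_k$ the class means, $\Sigma$ the pooled within-class covariance
and $\pi_k$ the priors (empirical by default; uniform by flag — the
balanced protocol makes them equal anyway). The pooled estimate from
$\sim$300 frames per class in 68 dimensions is near-singular, so
$\Sigma$ is shrunk as $(1-\lambda)\Sigma + \lambda\,\mathrm{diag}\Sigma$
with $\lambda = 10^{-3}$ by default, recorded in every model artifact.
Ties in $\arg\max_k \delta_k$ break to the lowest class index,
deterministically. The implementation is unit-tested against the analytic
Bayes rule on Gaussian mixtures and against `MASS::lda` predictions.

Four comparison classifiers run behind the same interface at fixed
settings: decision tree with entropy splits (unpruned), 3-nearest
neighbours (Euclidean), random forest with 40 trees and minimum leaf size
1, and a linear SVM with $C = 100$. They are library-backed baselines;
random-forest mean-decrease-in-Gini, normalized to sum to one, provides
the top-10 feature-importance ranking (`gini_importance()`).

## Evaluation protocols

* **Offline**: leave-one-*trial*-out cross-validation (`loto_cv()`) over
  the five trials, frames restricted to the trimmed [2, 5.5] s span. The
  trial is always the CV unit — frame-level CV would leak overlapping
  windows between train and test — and a structural assertion in every run
  verifies the split is disjoint. Sensor ablation (`ablate_sensors()`)
  re-runs the CV under all 7 column masks of {EMG, FMG, IMU} without
  re-extracting features.
* **Simulated real time** (`simulate_realtime()`): per held-out trial,
  a group-restricted model is trained on the other four trials; each
  movement is tested with its first 10 frames starting 1 s after onset and
  resolved into one majority-vote decision (ties break to the larger
  summed discriminant score). Per-trial statistics are acausal mid-stream,
  so test frames are normalized with statistics pooled from the training
  trials — a documented deviation from the offline per-trial rule.
* **Grouping** (`grouping_scheme()`): in-game rounds present only 3 of
  the 12 gestures, and gestures known to be mutually confusable (CG/SG,
  TA/O, ME/HG, HG/MF, HG/NM, TA/NM, WE/FP) must never share a group. The
  exact published group memberships are not available, so the default is a
  fixed partition satisfying every constraint — MF/TA/WE, ME/CG/FP,
  HG/O/FS, SG/WF/NM — overridable and emitted into every report.
  `greedy_grouping()` proposes partitions from an observed confusion
  matrix; `validate_grouping()` checks any proposal and scores its
  within-group confusion mass.

## Numerical and design choices

* Sessions are stored as plain CSV streams plus JSON metadata, floats
  formatted `%.9g` with fixed line endings: byte-stable writes,
  round-trips exact to 9 significant digits, everything diffable.
* All randomness flows through one seed per (subject, trial), derived
  deterministically from the master seed; generation never perturbs the
  caller's RNG state. Random-forest vote ties are resolved by first index
  because `predict.randomForest` would otherwise consume RNG.
* Degenerate inputs fail loudly at boundaries (short segments, missing
  labels in a training fold, single-frame trials, constant correlation
  inputs) and softly mid-stream (zero-variance channels, clipped FMG)
  with flags rather than exceptions.
* Problem sizes in the test suite: unit tests run a compact protocol
  (1.5 s movements, 0.5 s gaps) that preserves all structure; the
  end-to-end checks run the full 116 s / 5-trial / 10-subject protocol,
  with features computed once per subject and shared across the CV,
  ablation and real-time evaluations.

## Known limitations

The generator's class-conditional stationarity makes the task easier than
clinical reality: accuracies on synthetic cohorts (≥ 95 % fused at
$\gamma = 1$) characterize pipeline correctness and modality
complementarity, not expected patient performance. The streaming
normalization rule (pooled training statistics) is one defensible choice
among several the offline rule does not determine. The grouping default is
constraint-satisfying, not provably optimal; `greedy_grouping()` is a
heuristic, checked against brute force only at reduced label counts.
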