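# mmgesture

Hand-gesture classification from a wearable multimodal sensor set, built
for rehabilitation sensing research: six-channel surface electromyography
(EMG, 1926 Hz) on the forearm, an eight-channel barometric
force-myography (FMG) wristband and a twelve-channel inertial measurement
unit (IMU), both at 36 Hz. The gesture vocabulary is eleven
activities-of-daily-living hand/wrist/forearm movements drawn from the
Fugl-Meyer Assessment plus a rest class — twelve labels in all.

The package provides the full chain from raw synchronized streams to
cross-validated accuracy numbers:

- trigger-based movement segmentation with head/tail trimming (2 s / 0.5 s),
- multirate windowing — overlapped 222 ms EMG windows stepped by 55.6 ms
  (428 / 107 samples), disjoint 55.6 ms FMG/IMU windows (2 samples) —
  with causal cross-rate pairing,
- the classic time-domain feature set per EMG channel (MAV, WL,
  threshold ZC and SSC with ε = 4e−6 V, Burg AR(4)) plus FMG/IMU MAV:
  a fused 68-dimensional feature vector (48 + 8 + 12),
- per-trial zero-mean normalization,
- linear discriminant analysis implemented from its discriminant function
  δ_k(x) = xᵀΣ⁻¹μ_k − ½μ_kᵀΣ⁻¹μ_k + log π_k with pooled-covariance
  shrinkage, plus DT / KNN / RF / SVM baselines at fixed hyperparameters,
- leave-one-trial-out cross-validation, 7-row sensor ablation,
  random-forest Gini feature-importance ranking,
- a grouped simulated real-time protocol: 10-frame majority voting on
  frames starting 1 s after movement onset, with the 12 gestures
  partitioned into game rounds that keep confusable pairs apart,
- a seeded synthetic multimodal recording generator emulating the
  training protocol (12 movements × 6 s, 4 s gaps, 5 trials/subject), so
  everything above is testable without clinical data.

## Worked example

```r
library(mmgesture)

cfg  <- synth_config(seed = 7)                       # full 116-s trials
recs <- lapply(1:5, function(k)
  generate_trial(cfg, trial_id = k, subject_index = 1))
sf   <- subject_features(recs)                       # 68-dim frames/trial

loto_cv(sf$offline)$accuracy
#> [1] 0.9872222
ablate_sensors(sf$offline)
#>       sensors n_features  accuracy
#> 1         EMG         48 0.9122222
#> 2         FMG          8 0.6727778
#> 3         IMU         12 0.7119444
#> 4     EMG+FMG         56 0.9875000
#> 5     EMG+IMU         60 0.9119444
#> 6     FMG+IMU         20 0.8138889
#> 7 EMG+FMG+IMU         68 0.9872222
simulate_realtime(sf)$accuracy
#> [1] 1
```

Read: with all signatures at full strength, fused 12-class
leave-one-trial-out accuracy is 98.7 % and dominates every single
modality (EMG 91.2 %, IMU 71.2 %, FMG 67.3 %); restricting each in-game
decision to a 3-gesture group and voting over 10 frames lifts simulated
real-time accuracy to 100 %. The synthetic generator is engineered so the
grips CG/SG differ only in FMG and MF/HG only in EMG — the single-modality
drops and the fusion gain are the designed behaviour, not clinical claims.

A thin CLI over the same functions lives at `inst/cli/mmgesture.R`
(subcommands `synth`, `features`, `demo`), and `run_demo()` performs the
whole cohort-level analysis in one call.

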