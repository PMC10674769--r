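# armfatigue

Estimation of biceps-brachii muscle fatigue during repetitive lifting from
wearable, non-invasive sensors: an optical-fiber elbow-angle sensor (OFS),
surface EMG, and two 6-channel inertial units (wrist and neck). The package
is aimed at researchers in wearable-sensor ergonomics and biomedical signal
processing who want a fully reproducible version of this pipeline — from raw
multi-rate streams to cross-validated fatigue-state classification — plus a
synthetic cohort that makes every stage runnable and testable without
recorded data.

## What it computes

Subjects perform biceps curls to exhaustion while rating perceived exertion
on the Borg CR10 scale every 20 s; the trial stops at a rating of 10. The
pipeline:

1. **Conditions** each stream: two-point OFS calibration (0°/140°) and a
   zero-phase 0.5 Hz low-pass; EMG 15–450 Hz band-pass (4th-order
   Butterworth), MVC normalization, rectification and 200 ms envelope; IMU
   anatomical-baseline subtraction and 30 ms smoothing.
2. **Segments** repetition cycles as peak-to-peak windows of the elbow
   angle and labels each cycle LF / MOF / HF from the linearly interpolated
   Borg value at the window midpoint (cuts at 3 and 6 by default).
3. **Extracts 63 features per cycle**: mean, sample SD, RMS and amplitude
   per IMU channel (2 × 24); angle statistics, ROM, cycle duration and
   MNF/MDF/IMNF (8); EMG envelope statistics and MNF/MDF/IMNF of the
   band-passed signal (7). MNF is the spectral centroid
   `sum(f P(f)) / sum(P(f))`, MDF the half-power frequency, and IMNF the
   time-averaged instantaneous mean frequency from a complex-Morlet
   continuous wavelet transform. Time-amplitude features are normalized to
   each subject's first cycle (`fn = fi / f0`); frequency features pass
   through.
4. **Classifies** the three fatigue states with tree ensembles (leaf-wise
   gradient-boosted trees, random forest, bagged trees, extra-trees, single
   tree), tuned by leave-one-subject-out cross-validation inside a 70:30
   subject-level split (30 subjects → 21 train = 21 folds / 9 test), then
   ranks features by split importance and runs a sensor-ablation protocol
   (EMG / OFS / each IMU / IMU pair / IMUs+OFS / all).

## Worked example

```r
library(armfatigue)

run <- run_pipeline(synthetic_params(), seed = 1)

length(run$plan$train_subjects)   # 21
length(run$cv$fold_subjects)      # 21
nrow(run$features)                # 1135 cycles x 63 features
head(run$importance, 3)
#>   feature         splits
#> 1 IMU1_GyroZ_RMS      79
#> 2 IMU1_AccZ_Amp       60
#> 3 IMU2_AccZ_Amp       59
run$reports$all
#> <model_report> lgbm [all] - 33 features, 344 test cycles
#>   accuracy 95.6%  precision 95.7%  recall 95.6%  F1 95.7% (weighted)
mean(run$trends$recovered)        # 1: every subject shows the four
                                  # fatigue directions (EMG envelope up,
                                  # EMG IMNF down, cycle duration up,
                                  # ROM down)
```

The per-combination reports in `run$reports` give the held-out accuracy of
every sensor subset after importance-based reduction — e.g. with seed 1 the
IMU pair reaches 96.5% with 10 features and the EMG alone 88.1% with 7,
showing that kinematic channels carry most of the fatigue signal on the
synthetic cohort.

The same steps are available as a narrative workflow in `analysis/`
(`01_simulate_cohort.R` … `04_sensor_ablation.R`), each a thin driver over
the package functions that prints what it found and writes its tables under
`results/`.

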