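---
title: "Methods: estimating upper-limb muscle fatigue from wearable sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating upper-limb muscle fatigue from wearable sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Muscle fatigue — the declining ability to sustain force during voluntary
contraction — is usually assessed with surface EMG, whose spectral content
shifts to lower frequencies as muscle-fiber conduction velocity drops.
EMG electrodes, however, perform poorly over long shifts (sweat, electrode
contact), which motivates estimating fatigue from wearable alternatives: an
optical-fiber sensor (OFS) tracking the elbow angle and two inertial units
(wrist and neck). This package implements the full estimation pipeline for a
repetitive biceps-curl task driven to exhaustion: signal conditioning,
repetition-cycle segmentation, a 63-feature per-cycle catalog, Borg
CR10-derived three-state labels (low / moderate / high fatigue), subject-wise
cross-validated tree-ensemble classification, split-importance ranking and a
sensor-ablation protocol. A synthetic-cohort simulator makes the whole
pipeline runnable and testable without any recorded data.

## The synthetic cohort

The simulator is not a fixture: it encodes the fatigue physiology the
analysis assumes, with one latent driver. For each subject the latent
exertion ramp $r(t)$ rises monotonically from 0 to 10 over the trial, and
$u(t) = r(t)/10 \in [0,1]$ drives every fatigue effect:

* repetition period $p(u) = p_0 (1 + s\,u)$ with $p_0 = 4$ s and slowing
  rate $s = 0.5$ (cycles stretch by half at full fatigue);
* range of motion $\mathrm{ROM}(u) = 120^\circ - 30^\circ u$, extension
  pinned at $140^\circ$ so flexion becomes incomplete;
* EMG envelope $a(u) = (3 + 5u)\ \%\mathrm{MVC}$ — matching amplitudes that
  start below 3 %MVC and reach roughly 8 %MVC at exhaustion;
* EMG spectral center $f_c(u) = 90 - 25u$ Hz (synthesized as unit-variance
  low-pass noise modulated onto a cosine carrier with instantaneous
  frequency $f_c(u)$, two-sided bandwidth 80 Hz);
* neck compensation: oscillation at the cycle frequency with amplitude
  proportional to $u$ on all six neck channels.

The Borg trajectory is a power ramp reaching 9 at 80% of the exhaustion
time (exponent 1.4, chosen so the three states occupy roughly 37/28/35% of
cycles, the occupancy pattern typical of exhaustion protocols), then a slow
plateau from 9 to 10 — subjects linger near 9 before failure. Ratings are
snapped to the CR10 response grid and queried every 20 s; the trial
truncates at the first rating of 10. The nominal exhaustion time is 200 s,
which with the 4 s base period yields ~40 repetitions per subject and a
cohort of ~1100-1250 cycles for 30 subjects. Sampling rates are 1024 Hz
(EMG), 128 Hz (IMUs) and 100 Hz (OFS; the optical interrogator's rate is a
free choice, two hundred times the angle filter cutoff). Subjects differ by
multiplicative log-normal perturbations (sigma 0.08) of all dynamic
parameters, seeded per subject for bitwise reproducibility.

What the simulator deliberately does **not** model: electrode artifacts,
sweat-induced drift, Hill-type muscle dynamics, inter-muscle crosstalk,
postural strategies beyond a single neck oscillation, or label noise in the
Borg responses. Passing tests on this cohort therefore demonstrate that the
pipeline recovers the assumed fatigue structure — not that the reported
accuracies transfer to recorded data.

## Signal conditioning

* **OFS**: two-point affine calibration (voltages at 0° and 140°), then a
  zero-phase 4th-order Butterworth low-pass at 0.5 Hz. The filter family
  and order for the angle channel are our choice, made to match the EMG
  filter; the cutoff keeps the ~0.25 Hz cycle and rejects everything above.
* **EMG**: 15–450 Hz band-pass (4th-order Butterworth, zero-phase,
  implemented as cascaded high-/low-pass halves for numerical robustness at
  the wide relative band), then division by the subject's MVC,
  rectification and a 200 ms moving average — the envelope in %MVC. The MVC
  is the mean of three repeated contractions, each summarized by the mean
  of the central 60% of its hold (the hold protocol specifies durations but
  no summary statistic; the central-window mean discards ramp and release).
* **IMU**: per-channel subtraction of the 1-min anatomical baseline, then a
  30 ms centered moving average (5 samples at 128 Hz after rounding to the
  nearest odd width). Edges shrink the window instead of padding.

All filters are zero-phase (forward–backward) so cycle boundaries stay
aligned across sensors; the effective order doubles but the printed corner
frequencies are kept. Because a textbook forward–backward pass has large
edge transients, the implementation extends each series by odd reflection
and starts each pass from the filter's steady state, which reproduces
constants to ~1e-9 and confines transients to the padding.

## Cycle segmentation and labels

Repetition cycles are peak-to-peak windows of the filtered angle. Peaks are
interior local maxima filtered by topographic prominence (≥ 20% of the
signal range) and minimum separation (≥ 0.5 × the cycle period estimated
from the autocorrelation's first peak). Both thresholds are scale-free, so
detection survives the ROM shrinking and the period stretching; neither is
prescribed by the protocol, which specifies only "peak to peak". Windows
are variable-length and non-overlapping by construction — with fatigue the
repetition duration itself is a feature, so fixed windows are not an
option. Using maxima (extension) rather than minima shifts all windows by
half a cycle and nothing else.

Borg ratings are linearly interpolated between queries, clamped outside;
each cycle takes the interpolated value at its midpoint (midpoint rather
than edge avoids biasing the label toward either neighbor). States default
to LF ≤ 3 < MOF ≤ 6 < HF, the CR10 verbal-anchor convention; the cuts are
configurable because the protocol defines them only graphically.

## The feature catalog

63 features per cycle: for each IMU channel (3 gyro + 3 acc, wrist then
neck) the mean, sample standard deviation, RMS and amplitude (max − min);
for the angle the same four statistics plus the cycle duration
(`FIB_tnorm`), and MNF, MDF, IMNF; for the EMG the four statistics of the
envelope plus MNF, MDF, IMNF of the band-passed signal. Spectral features
use a Hann-tapered periodogram with the zero-frequency bin excluded
(MNF/MDF describe oscillatory content; the angle's large DC offset would
otherwise dominate through leakage). MNF is the power-weighted mean
frequency; MDF the smallest frequency reaching half the cumulative power.

The IMNF comes from a complex-Morlet CWT (center frequency 1, bandwidth
1.5) on a log-spaced frequency grid: at every sample the power-weighted
instantaneous frequency is formed and the per-sample values are averaged
over the window. Two numerical choices matter. First, the scalogram is
divided by frequency (constant-Q bandwidth correction) and integrated with
trapezoid quadrature over the log grid, so the instantaneous centroid is
comparable to the Fourier MNF — without the correction the constant-Q
kernel inflates broadband centroids by 10–15%. Second, the grid's lower
edge defaults to half a cycle per window length, so a single repetition's
sub-hertz angle fundamental is inside the analyzed band; EMG features use a
1 Hz floor. Tone, chirp and band-noise oracles bound the residual bias at
3–4%.

Normalization: every time-amplitude feature is divided by the same
subject's first-cycle value ($f_n = f_i / f_0$), making trajectories
relative to the rested state; frequency features are inter-subject
comparable already and pass through. A zero first-cycle value is refused
with the feature named rather than epsilon-padded — silent padding would
manufacture arbitrary magnitudes. Because $f_0$ comes only from the
subject's own first cycle, normalizing before the train/test split leaks
nothing across subjects.

## Classification

Subjects (never cycles) are split 70:30 — 30 subjects give 21 training and
9 test subjects. Hyperparameters are tuned by leave-one-subject-out
cross-validation: folds equal training subjects (k = 21), all candidates
share the folds, selection is by mean fold accuracy with weighted-F1 and
then grid-order tie-breaks. Five tree-ensemble families are wired: leaf-wise
gradient-boosted trees (the tuned default; grid around 181 leaves and
min-child 8), random forest (up to 1400 trees, depth 40), bagged trees (10
deep trees, 70% feature draws), extremely randomized trees (200 trees) and
a single decision tree (gini, leaf size 1). Grids are deliberately small
neighborhoods of known-good settings so the whole search stays desk-scale.

Feature importance is split importance: the number of times a feature is
used across the boosted ensemble, with ties kept in canonical catalog
order. The ablation protocol restricts the table to each sensor
combination, re-ranks within the combination, keeps the top k (defaults 7
EMG, 8 OFS, 5 wrist IMU, 4 neck IMU, 10 IMUs, 13 IMUs+OFS, 33 all),
retrains with the tuned hyperparameters and evaluates on the held-out
subjects. A per-combination grid search is not repeated — the ranking and
retraining, not re-tuning, are the protocol.

## Metrics

Accuracy is the diagonal fraction of the 3×3 confusion matrix. Precision
and recall are reported under two averagings, micro (pooled counts — for
single-label multiclass data micro precision = micro recall = accuracy, an
identity the tests assert on a thousand random matrices) and weighted
(per-class ratios weighted by true-class support), with F1 the harmonic
mean of the aggregated pair. Both are reported side by side because the two
conventions genuinely disagree whenever class support is unbalanced, and
reporting one as the other is a common source of irreproducible tables.

## Problem sizes and determinism

The default study conditions — 30 subjects, ~200 s to exhaustion, ~1100+
cycles — run the full pipeline (generation → features → 21-fold LOOCV over
the grid → ablation over seven combinations) in a few minutes on one core.
Everything is seeded: cohort generation derives per-subject seeds from the
master seed, training fixes the RNG and runs single-threaded, so repeated
runs are bitwise identical. The test suite exercises the same default
conditions once and reuses the run across acceptance checks.

## Known limitations

* The synthetic EMG is narrowband modulated noise; real EMG has heavier
  tails, motion artifacts and nonstationary bursts within a cycle.
* The latent exertion ramp is smooth and monotone; real Borg responses
  plateau, regress and quantize more coarsely.
* Borg state boundaries (3, 6) are a convention, not an identified
  quantity; results with recorded data should sweep them.
* Split-importance counts favor high-cardinality features; gain-based
  importance would rank differently and is not implemented because the
  protocol specifies split counts.
* Accuracies measured on the synthetic cohort characterize the pipeline's
  ability to recover planted structure, not field performance.
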