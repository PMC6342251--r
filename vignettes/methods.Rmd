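---
title: "Cluster-based adaptive sleep staging for preterm EEG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster-based adaptive sleep staging for preterm EEG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(classqs)
```

## The problem

Quiet sleep (QS) in preterm neonates is the sleep state in which the EEG is
relatively discontinuous: high-amplitude slow bursts alternate with
low-amplitude interburst intervals (IBIs) — the *tracé discontinu* pattern —
while active sleep, indeterminate sleep and wakefulness (collapsed here into
a single non-QS state) show more continuous mixed-frequency activity.
Because several background abnormalities are visible only in QS, and because
QS is comparatively artifact-poor, automatic QS detection is the natural
first step toward automated assessment of functional brain maturation over
postmenstrual age (PMA = gestational age + postnatal age, in weeks).

`classqs` detects QS from multichannel EEG by exploiting a single working
assumption: **QS remains relatively more discontinuous than non-QS across
the preterm PMA range**. Everything in the pipeline serves to convert
"relative discontinuity" into a thresholdable scalar trace.

## Pipeline

1. **Pre-processing** (`bandpass_notch`, `drop_bad_channels`): 1–40 Hz
   zero-phase Butterworth band-pass (4th order) with a 50 Hz notch (Q = 30);
   channels with more than 20% non-finite signal (electrode drop-off) are
   discarded and remaining gaps linearly interpolated.
2. **Artifact subspace reconstruction** (`asr_calibrate`, `asr_clean`):
   a robust PCA of a clean ~1 min calibration epoch yields per-component RMS
   thresholds `t_c = mu_c + asr_thresh * sigma_c`; a sliding-window PCA of
   the recording rejects window components whose variance exceeds the
   projected thresholds and reconstructs each sample from the retained
   subspace through `R = M (V'M ∘ A)^+ V'`.
3. **Downsampling** (`downsample`): decimation by 3 (250 → 83.33 Hz) with an
   anti-alias guard.
4. **Adaptive segmentation** (`segment_channel`): two contiguous sliding
   windows are compared through an amplitude measure (sum of absolute
   amplitudes) and a frequency measure (total variation); peaks of the
   weighted difference signal `G = |ΔADIF| + kF·|ΔFDIF|` above
   `MINPEAKHEIGHT`, at least `MINPEAKDISTANCE` apart, become segment
   boundaries. Segments are typically 1–5 s.
5. **Cluster-time profiles** (`extract_features`, `cluster_segments`,
   `build_profiles`): nine time/frequency features per segment, pooled over
   channels, z-scored, k-means clustered (k = 12, best of 20 restarts),
   clusters relabeled by increasing mean segment variance. Replacing each
   sample by its segment's label gives an integer profile whose fluctuation
   tracks discontinuity.
6. **QS classification** (`stitch_and_threshold`,
   `postprocess_min_duration`): channel-average profile, de-trend by a
   500-sample running mean, square, smooth with a 35,000-sample moving
   average (~7 min at 83.33 Hz); recordings longer than 2 h are enveloped
   per 2 h block and stitched; one global threshold — the mean of the
   stitched envelope — marks QS, and detections shorter than 3 minutes are
   removed.

The tuned parameter set lives in `default_config()`; every stage is also
exposed individually.

## Tuned parameters

| parameter | stage | default | unit / note |
|---|---|---|---|
| `asr_thresh` | ASR | 10 | SDs above mean component RMS |
| `win_s` | segmentation | 0.7 | s, sliding-window length |
| `shift_samples` | segmentation | 9 | samples between window positions |
| `kf` | segmentation | 10 | weight of the frequency measure |
| `minpeakheight` | segmentation | 100 | µV-scale G units (signals must be in µV) |
| `minpeakdistance_samples` | segmentation | 25 | G-grid samples (~2.7 s) |
| `k` | clustering | 12 | clusters |
| `avg_win_length` | classification | 500 | samples, de-trending MA |
| `smooth_win_length` | classification | 35000 | samples, envelope MA |

`minpeakdistance_samples` is interpreted on the grid on which `G` is
defined (one point per `shift_samples`), i.e. ~2.7 s between successive
boundaries — the reading consistent with 1–5 s typical segments; a
25-sample spacing of the 83 Hz signal (0.3 s) would not be.

## Numerical and design choices

* **Filter realization.** The band-pass/notch realization is a 4th-order
  Butterworth cascaded with an RBJ notch biquad, applied forward-backward
  (zero phase). On hours-long signals the same squared-magnitude transfer
  function is applied spectrally (FFT with zero padding), which is the
  identical zero-phase response at a fraction of the cost; short signals use
  time-domain `filtfilt`.
* **Geometric-median covariance.** Calibration PCA uses the matrix
  minimizing summed Frobenius distances to the per-sample outer products
  (Weiszfeld iteration, tolerance 1e-6, ≤500 iterations; coordinate-wise
  median fallback with a warning). For Gaussian data this estimator is a
  *shrunk* version of the mean covariance (outer products are heavily
  right-skewed); that scale difference is immaterial here because only the
  eigenbasis and the relative component thresholds matter.
* **Threshold fitting.** Component RMS values (0.5 s segments, 66% overlap)
  are summarized by a Gaussian fitted on the central 1st–95th percentile
  mass, keeping thresholds robust to residual artifact extremities.
* **Square root of the covariance.** `M` is the symmetric eigendecomposition
  root — any root satisfies `Y = MM'`; fixing one makes runs reproducible.
* **Rejected subspace.** The reconstruction matrix annihilates rejected
  input directions exactly (`R v = 0` for a rejected eigenvector `v`); the
  cleaned sample re-estimates content in those directions from the
  correlation structure of the calibration data. Rejection can only remove
  window variance, never add it.
* **Cleaning stride.** Recomputing `R` at every sample is the faithful
  default but O(n·c³). With `asr_stride > 1` a coarse pass first locates
  the windows that reject components — every all-keep window has `R = I`
  and needs no work — and only rejection neighborhoods are re-cleaned at
  2-sample resolution. This keeps artifact onsets sharp (a plain
  stride-reuse scheme leaks fraction-of-a-second artifact stubs that later
  read as discontinuities) at a fraction of the sample-by-sample cost. The
  command-line default stride is `fs/4`; fidelity tests run stride 1.
* **Calibration selection.** Rather than a fixed exemplar recording, a
  60 s epoch is auto-selected per recording (manual override available):
  epochs containing any 0.5 s window beyond a robust z-score of 15 (an
  order of magnitude above background — movement-artifact territory) are
  excluded, and among the rest the epoch with the *largest* per-channel RMS
  dynamics wins. The thresholds `t_c = mu_c + asr_thresh·sigma_c` must span
  the recording's normal burst/interburst amplitude range; calibrating on a
  merely quiet stretch would under-estimate `sigma_c` and reject genuine
  EEG discontinuities as artifacts.
* **Edge policy.** All moving averages reflect at the edges, so envelopes do
  not collapse at recording boundaries (which would bias the global mean
  threshold). Intervals are half-open `[start, end)` seconds.
* **Feature z-scoring.** Without standardization the µV-scale features
  dominate the Euclidean metric; clustering is therefore performed on
  z-scored features, making it invariant to per-feature affine rescaling.
* **Segments shorter than 4 samples** are merged into their predecessor
  before feature extraction (the second difference needs three intervals).
* **SD-only ablation.** The clustering-free variant quantile-bins per-segment
  standard deviations into k ordered levels, the nearest faithful reading of
  "using only the segment standard deviations".
* **Threshold semantics.** The QS threshold is strictly `envelope > mean`,
  computed once over the whole stitched envelope; a constant profile
  therefore yields no QS, and adding a constant to the profile changes
  nothing (the de-trending removes it).
* **Event matching.** A detected and a reference period match when their
  intersection exceeds 50% of the *shorter* of the two durations — symmetric,
  and a short fully-contained detection can still match. The ROC sweep varies
  only the envelope threshold (no 3-minute rule inside the sweep); the
  operating point reported elsewhere includes the rule.
* **SAT% baseline.** The burst detector marks samples whose 0.5 s-smoothed
  channel-mean |NLEO| exceeds `max(10 µV², 0.5 × running 60 s mean)`. The
  absolute floor separates suppressed IBI activity from bursts; the running
  *mean* (not median) stays between the burst and IBI energy modes whatever
  their occupancy, which a median does not when occupancy is near 50%. These
  internals are a reconstruction of burst-detector practice with explicit,
  configurable defaults, not a published recipe.
* **Trend regression.** Mixed model with subject random intercept (REML,
  Satterthwaite p-values), PMA centered at 34 weeks before squaring;
  coefficients are back-transformed to the raw-PMA parameterization
  `y = a + b1·x + b2·x²`. Singular fits fall back to OLS with
  subject-clustered robust standard errors and are flagged. The analysis
  window defaults to 31–38 weeks, the range where detection is most
  reliable.

## The simulator, and what passing tests do (and do not) show

`simulate_recording()` generates multichannel EEG as band-limited Gaussian
noise under a state-driven amplitude envelope:

* **QS**: alternating bursts (2 s, 50 µV RMS, slow 0.5–3 Hz-dominated
  content) and IBIs (3 s, 8 µV RMS); **non-QS**: continuous mixed 1–15 Hz
  activity at 20 µV RMS. State durations are truncated normals (QS mean
  20 min — the average QS duration — non-QS mean 30 min).
* Channels share the state timing and 30% of their source variance
  (inter-channel correlation 0.3).
* **PMA mapping**: IBIs lengthen by 30%/week below 31 weeks; above 38 weeks
  the QS/non-QS amplitude contrast shrinks by 25%/week (floor 0.25),
  emulating the globally more continuous near-term EEG.
* **Artifacts**: 2 s broadband transients at 20 times the non-QS amplitude
  on random channel subsets, arriving at 10/h overall but clustered inside
  movement bouts (2/h, 120 s) — the handling/wake pattern that actually
  disrupts discontinuity-based staging; isolated transients are averaged
  away by the 7-min smoothing. A ground-truth artifact mask is returned.
* `contrast` interpolates the QS parameters toward the non-QS ones;
  `contrast = 1` makes QS statistically identical to non-QS (the
  uninformative limit used to check chance-level behavior), 2 is nominal.
* A single seed drives independent sub-streams (states, waveforms,
  artifacts), so realizations are bit-reproducible.

The simulator reproduces the amplitude-and-slow-frequency signature that the
detector keys on, with known ground truth — which is exactly what the test
suite needs. It does **not** model true tracé alternant morphology, sleep
spindles/delta brushes, state-dependent artifact rates, inter-subject
electrode variation, or indeterminate-sleep transitions. Passing the
end-to-end suite therefore demonstrates correctness of the mechanics and
sane behavior under the stated phenomenology, not clinical-grade accuracy on
real neonatal recordings.

Cohort-scale validation of the trend machinery uses `simulate_trend_data()`,
which draws per-recording characteristic values directly from the mixed
model (subject intercept SD 0.1, residual SD 0.1, planted log-Burst% slope
0.045/week); EEG-level cohorts at hundreds of replicates are not computable
at package-check scale, and the value-level design is the sharper test of
the estimator anyway.

## Problem sizes used in the shipped checks

The end-to-end experiment in the test suite runs 12 simulated recordings of
4 h (PMAs 29–41 weeks) with the tuned configuration at an ASR stride of
`fs/2`, plus three artifact-dense 2 h fixtures for the ablation ordering;
the acceptance script runs eight 3 h recordings at 31–38 weeks plus two
ablation fixtures. Trend calibration uses 100 recovery and 500 null
replicates of ~50-recording cohorts.

## Known limitations

* Active-sleep detection is out of scope; the state alphabet is binary.
* A single calibration epoch serves the whole recording; recordings whose
  artifact character drifts over hours may benefit from re-calibration.
* The mean-envelope threshold assumes both states are present in the
  recording; a recording that is entirely QS (or entirely non-QS) will
  still be split at the threshold.
* `MINPEAKHEIGHT` is amplitude-dimensional: inputs must be in microvolts.
* EDF support covers continuous recordings with a homogeneous EEG sampling
  rate; EDF+ discontinuous files are not parsed.
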