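---
title: "Stride segmentation methods for foot-worn IMU gait recordings"
author: "gaitseg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stride segmentation methods for foot-worn IMU gait recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitseg)
```

## The problem

Mobile gait analysis with foot-worn inertial measurement units (IMUs) starts
by cutting a continuous 6-channel recording — tri-axial acceleration (g) and
tri-axial angular velocity (deg/s) — into individual strides. In clinical
populations such as Parkinson's disease this is hard precisely where it
matters: walking tests like the Timed Up-and-Go (TUG) mix straight strides
with turning strides, sit-to-stand and stand-to-sit transitions and quiet
standing, and stride shape varies both between patients and within a single
walk. `gaitseg` implements four segmentation approaches spanning the three
families in common use — event detection, template matching and
probabilistic sequence modeling — behind one train/predict interface, plus
the evaluation protocol needed to compare them fairly.

The sagittal-plane gyroscope channel `GZ` is the anchor signal throughout: a
stride runs from the negative `GZ` trough before swing to the negative
trough at the end of stance, and the dominant positive `GZ` peak marks
mid-swing. Consecutive strides share a border sample; intervals are
represented half-open `[start, end)` in 0-based samples so a shared border
is expressible without overlap. All duration thresholds are given in
milliseconds and converted once, through `ms_to_samples()` (round half away
from zero), so every module sees identical sample counts.

## The four segmenters

**Peak detection** (`detect_peaks()`) accepts a sample as a mid-swing event
if it is a strict local `GZ` maximum above 150 deg/s and no stronger
accepted peak lies within a 600 ms refractory period (600 ms being the lower
bound of a plausible stride). Conflicts are resolved greedily in descending
amplitude, so where several candidates compete only the highest survives.
Plateaus count once, at their first sample. The method has no training
phase; it detects one point per stride rather than stride borders, and it is
scored accordingly (below).

**Multi-subsequence DTW** (`segment_msdtw()`) warps a stride template of
length M = 200 against the recording. The accumulated cost matrix uses a
free start along the template's first row, so the matching function
(the cost row of the full template) has one local minimum per occurrence;
minima below a threshold are backtracked (tie preference: diagonal,
vertical, horizontal) to obtain warping paths. Candidate matches are kept
only if their duration lies strictly between 600 and 2500 ms, and pairwise
temporal overlaps of 200 ms or more are resolved in favor of the lower-cost
match. Two cost families are provided:

* *Euclidean* (`build_average_template()`): training strides are linearly
  interpolated to M samples, averaged position by position and normalized to
  the sensor ranges (±6 g, ±500 deg/s). The pointwise per-axis distance is
  the absolute difference, summed over the selected axes (squared
  differences are available by configuration); the default axis set is
  `GZ` alone, since `AZ`, `GX` and `GY` are nearly constant in foot-worn
  gait data and `AX`/`AY` can be added per configuration. Default
  threshold 15, the midpoint of the published 10–25 grid for `GZ`.
* *Probabilistic* (`build_probabilistic_template()`): the sample vector at
  each template position is modeled by a diagonal Gaussian (variance floored
  at 1e-4 in normalized units, so nearly identical training strides cannot
  produce degenerate densities). The similarity of a sample is the
  likelihood rescaled by its value at the mean, `P(y) = exp(-Mahalanobis²/2)
  ∈ (0, 1]` — a raw density is *not* bounded by 1, so the rescaling is what
  makes a bounded similarity well-defined — and the distance is
  `D = exp(-P) ∈ [e^{-1}, 1)`.

One scale decision deserves emphasis: the recording is normalized to the
sensor range before DTW so that sequence and template live on the same
scale; otherwise no fixed threshold is meaningful. And because every
probabilistic-cost path step costs at least `e^{-1}`, a path of length L has
cost at least `L·e^{-1}` (≈ 73.6 for L = M = 200) before any mismatch
penalty; thresholds in the published 8–15 range are therefore applied to the
baseline-adjusted path cost `Δ − L·e^{-1}`, which is zero for a perfect
match. Even so, the probabilistic cost is intrinsically conservative on
noisy data: when test deviations are drawn from the same distribution as the
training variance, the expected per-step adjusted cost is ≈ 0.1, i.e. ≈ 20
over a typical path — above the whole threshold grid — so pDTW recalls only
the closest-to-average strides on the noisy synthetic preset. This is a
property of the bounded-similarity mapping, not a tuning accident, and it is
visible in the benchmark report.

**Hierarchical HMM** (`train_bw()`, `viterbi_decode()`). A two-level model:
top-level states are movement classes (stride / transition / rest), each
expanded into a left-to-right chain of sub-states with Gaussian-mixture
emissions (diagonal covariance). The topology is flattened into one sparse
transition matrix: within a chain a sub-state may persist or advance; the
last sub-state may exit to the first sub-state of any class, including its
own — which is how back-to-back strides are expressed, as a sub-chain reset.

Features are extracted from hop-spaced Hann-windowed frames of all six
axes: the windowed samples themselves, their mean, variance, energy and the
three coefficients of a second-order polynomial fit, concatenated across
axes, z-scored with training-set statistics, and projected onto principal
components fitted on the training frames only. Whether the summary
statistics are computed on Hann-weighted or unweighted samples is
configurable (`hann_on_stats`); the default weights them, the flag exists
because either reading of "windowed features" is defensible.

Training is semi-supervised: frame-level class labels clamp the top level
(the emission likelihood of all other classes' sub-states is set to zero
during training), while sub-state alignment and GMM parameters are learned
by unconstrained Baum-Welch within the clamp — at most 20 iterations, with
an additional relative log-likelihood tolerance of 1e-4. The clamped
log-likelihood is non-decreasing over iterations (an EM guarantee the test
suite checks numerically, to 1e-6). Initialization follows the labels: the
top-level transition matrix from labeled frame bigrams, sub-states by
uniform temporal slicing *within each labeled segment* (segment identity
matters: consecutive strides share borders and so form one uninterrupted run
of stride-class frames), GMMs by k-means on the frames so assigned, and
second-level transitions uniform over the allowed entries. Decoding is
plain unconstrained Viterbi; each maximal pass through the stride sub-chain
becomes one stride, with borders placed at midpoints between neighboring
frame centers (so back-to-back passes share a border sample) and the
600–2500 ms duration filter applied, as for the DTW methods.

### Default hHMM configuration

The published search grid couples window length and sub-state count: a
left-to-right chain of k sub-states needs at least k frames per stride, so
at a 0.3 s window with 50% hop (~150 ms per frame) a typical 1.1 s stride
spans ~7 frames and cannot traverse 8 sub-states. The package default is
therefore a 0.10 s window (10 samples at 102.4 Hz, hop 5 samples ≈ 49 ms)
with the mid-grid values elsewhere: 8 stride sub-states, 3 transition
sub-states, 1 rest sub-state, 10 GMM components per sub-state, 7 principal
components. The short window also bounds the border quantization error at
half a hop (~24 ms), comfortably inside the ±100 ms scoring tolerance.
`hhmm_grid()` exposes the full published ranges for grid search. Remaining
numerical choices: covariance floor 1e-6 in normalized feature units, GMM
responsibilities in the log domain, k-means initialization seeded
explicitly, and a per-sub-state component count capped at the number of
distinct assigned frames.

## Evaluation protocol

A detected stride is correct if both borders fall within ±100 ms of an
unmatched ground-truth stride (roughly 10% of a stride time); matching is
greedy in temporal order, which coincides with optimal matching because the
tolerance is far smaller than the minimum stride duration. Peak detections
carry no borders; a peak is a true positive iff it falls strictly inside
exactly one unmatched ground-truth stride, extra peaks in the same stride
are false positives, and unmatched strides are false negatives. Precision,
recall and F-score follow from counts summed within each fold
(`compute_metrics()`), with explicit zero-denominator conventions: empty
detection on an empty truth set is perfect, empty detection against
existing strides has zero precision-from-nothing, and F is zero when both
components are.

`run_loocv()` implements leave-one-subject-out validation (both feet of the
held-out subject are scored; templates, models and parameters come from the
remaining subjects only). `run_nested_cv()` implements subject-level nested
cross-validation: an outer 4-fold split, an inner 4-fold grid search
maximizing mean validation F-score (ties toward the smaller model), and a
single scoring pass on the outer test fold; the fold randomization depends
only on the seed and is therefore identical across methods.
`compare_methods()` runs pairwise two-sided Wilcoxon signed-rank tests on
per-fold scores, with Pratt handling of zero differences and an exact
sign-flip null for up to 20 non-zero pairs — implemented in-package because
the base-R test offers no Pratt option — and no multiplicity correction.

## The synthetic generator

No public recordings exist for this problem, so the package ships a
parametric generator (`generate_straight_walk()`, `generate_tug()`,
`generate_cohort()`) whose defaults are the study conditions used by the
test suite and the acceptance script. A stride is a sum of smooth Gaussian
bump kernels over normalized phase: one dominant positive mid-swing `GZ`
peak (default 350 deg/s, well above the 150 deg/s detection threshold),
negative troughs at both borders (default −120 deg/s), smooth quasi-periodic
accelerometer waveforms, and near-constant `AZ`/`GX`/`GY`. Turning strides
are stretched (×1.3 duration) and attenuated (×0.75 gyro amplitude)
straight strides with an added frontal-plane `GX` excursion; sit-stand
transitions are low-frequency, high-amplitude accelerometer excursions with
`|GZ|` deliberately below the peak-detection threshold, per the convention
that a transition is any movement other than a stride. Variability knobs:
per-stride duration jitter (default 5%) and amplitude jitter (2%), additive
white noise (5 deg/s gyro, 0.02 g accel), and log-normal per-subject
duration (7%) and amplitude (5%) random effects drawn once per subject
before any stride-level noise, so cohort structure is stable when only
noise settings change.

What passing tests on these data do and do not show: the generator
guarantees by construction that every clean stride contains exactly one
detectable mid-swing peak and that borders carry negative troughs, so
perfect scores on the homogeneous preset demonstrate correct
implementation, not clinical performance. Real Parkinsonian data contain
shape irregularities, spurious `GZ` peaks during turns and transitions, and
drift that the generator does not emulate — notably, because synthetic
transitions never cross the 150 deg/s threshold, peak detection suffers no
precision penalty here, whereas on real heterogeneous data it does. The
heterogeneous-sequence comparison in the test suite is reported with
exactly that caveat.

## Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` use a 10-subject × 2-feet
straight-walk cohort with 22 strides per recording (440 scored strides) for
the leave-one-subject-out benchmark, 4-subject TUG cohorts across five seeds
for the heterogeneous comparison, 100 random instances (M ≤ 10, T ≤ 50) for
the exhaustive DTW cross-check, and 20 seeded runs for the EM monotonicity
check — sizes at which every property is exercised while the whole suite
runs in minutes on one CPU. Every random quantity is derived from an
explicit integer seed; rerunning any harness with the same seed reproduces
identical folds, cohorts and fits.

## Known limitations

* The synthetic stride family is parametric and smooth; it is not a
  biomechanically validated gait model, and freezing-of-gait or dyskinesia
  episodes are out of scope.
* The probabilistic DTW cost is conservative under the bounded-similarity
  mapping (see above); its published threshold range mainly recalls
  strides close to the template mean.
* Peak detection is scored by the peak-in-stride rule because a borderless
  detection cannot be matched by the ±100 ms border criterion; this is an
  explicit convention of the benchmark.
* The hHMM decodes offline (full-sequence Viterbi); online decoding and
  patient-individualized adaptation are not implemented.
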