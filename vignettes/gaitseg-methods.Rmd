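---
title: "Event-based gait segmentation and activity classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-based gait segmentation and activity classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitseg)
```

## The problem

A single inertial measurement unit strapped to the shank records six
channels at 100 Hz: tri-axial acceleration (m/s²) and tri-axial angular
velocity (rad/s). During locomotion the sagittal-plane angular velocity
`g_z` has a stereotyped shape per stride: a large positive lobe while the
shank swings forward (its maximum is the *mid-swing*), a sharp negative dip
at ground contact (*foot strike*), a low-amplitude stance, and a second
negative dip when the toe leaves the ground (*foot-off*). `gaitseg`
segments the signal into gait cycles — the spans between consecutive
foot-off events — with a streaming rule-based automaton, describes each
cycle with 152 features, and classifies the ongoing activity (level
walking WK, stair ascent SA, stair descent SD, running RUN) with a
pairwise SVM. A companion harness quantifies how little the usual
pre-processing (inclination correction, low-pass filtering) matters for
either step.

## Pre-processing

**Inclination correction.** The recording protocol begins with 5 s of
quiet standing. The per-channel mean over that window captures the gravity
projection and any constant mounting bias; `correct_inclination()`
subtracts it from all six channels. Nothing else is estimated — no
rotation, no drift model — because a constant additive offset is exactly
what a mis-inclined but rigidly mounted sensor adds.

**Online low-pass filter.** `design_lowpass()` builds a causal recursion
`y[n] = Σ b_k x[n−k] − Σ a_k y[n−k]`. The order-1 design is the bilinear
transform of a single-pole RC prototype, pre-warped so the corner lands
exactly at the requested cutoff (−3.01 dB there). The default order-2
design is the square of that section, collapsed to two feed-forward and
two feedback taps. The square of a first-order section was chosen over a
maximally-flat second-order design because only the former reaches the
published selectivity of −15 dB at twice the 10 Hz corner (the measured
value is −15.56 dB; a Butterworth biquad stops at ≈ −14 dB). Filter state
is explicit, so chunked streaming is bit-identical to batch processing;
initial history is zero, which is harmless because the startup transient
falls inside the discarded standing lead-in.

## The streaming detector

`step_detector()` is a three-phase automaton over single samples with
constant-size memory (no windows, no lookback):

1. **SEEKING_SWING** — track a rising zero crossing, then the running
   maximum of the positive lobe. When the falling crossing closes the
   lobe, accept the swing if the maximum exceeded 1.8 rad/s and emit
   `MID_SWING` at the argmax; otherwise keep seeking.
2. **SEEKING_FOOT_STRIKE** — emit `FOOT_STRIKE` at the first local
   minimum confirmed after the falling crossing.
3. **SEEKING_FOOT_OFF** — maintain the most recent confirmed local
   maximum `t_max` and following minimum `t_min`; emit `FOOT_OFF` at
   `t_min` when `t_min − t_max ≥ 60 ms`, `g_z(t_min) ≤ 1.4 rad/s` and
   `t_max − t_fs ≥ 70 ms` all hold. If 1.3 s elapse after the swing
   confirmation without a foot-off, the pending swing is discarded.

Local extrema are confirmed one sample after their trend reversal;
plateaus take the first plateau sample and ties the earliest index, so
detection latency is bounded by one sample plus the rule checks and the
automaton is fully deterministic. The "negative then positive
zero-crossing" wording of the underlying rule set is implemented as
rising-then-falling crossings around a positive lobe — the only reading
compatible with a positive swing peak. The timeout is anchored at the
swing confirmation (the falling crossing), which bounds worst-case cycle
latency. The signed comparison `g_z(t_min) ≤ 1.4` is used as printed, not
an absolute value.

Cycles are assembled from adjacent foot-off pairs. When per-sample labels
exist, a cycle takes the majority label, ties broken toward the label
whose run starts earliest; cycles whose majority label is not a
locomotion activity (e.g. spans of standing between bouts) are excluded
from classification.

## Features

Eight channels enter feature extraction: the six sensor axes plus the
orientation-independent acceleration and gyroscope magnitudes. The
152-dimensional vector decomposes as:

* 6 time statistics × 8 channels = 48: mean, median, skewness, kurtosis,
  standard deviation (n−1 denominator), interquartile range
  (linear-interpolation quantiles). Skewness and kurtosis are the third
  and fourth standardized sample moments (kurtosis non-excess); both are
  defined as 0 for a constant channel so the feature space stays closed.
* Pearson correlation of each ordered channel pair = 56. The symmetric
  duplicates are redundant but keep the layout rectangular in the
  channels; correlations involving a zero-variance channel are 0.
* Spectral energy plus DFT magnitudes 1–5 × 8 channels = 48. The DFT is
  taken on the unpadded variable-length cycle; with ~1 s cycles at 100 Hz
  bins 1–5 cover ≈ 1–5 Hz, the band carrying locomotion's main
  components. DC is excluded (the mean is already a feature), magnitudes
  are scaled by 1/n to be amplitude-like across variable-length cycles,
  and the energy is Parseval-normalized so it equals the time-domain mean
  square.

The published feature count is never itemized at the source; this
decomposition is a declared convention of the package that reproduces the
total exactly while covering the stated feature families.

Feature ranking trains one linear-kernel soft-margin machine per
unordered class pair on z-score-standardized features (the squared-weight
criterion is only meaningful for linear machines, and standardization
makes weights comparable across features); the importance of feature *j*
is the sum of squared primal weights over the machines. `select_top()`
keeps the first *k* (default 20).

## Classifier and evaluation

`train_classifier()` is a one-vs-one SVM with a polynomial kernel
`(x·y)^d`. The published configuration fixes the complexity (soft-margin
cost) at 1 but not the degree; degree 1 — the common default of the
toolkit named there — is the package default and both are exposed in
`classifier_spec()`. The dual problems are solved by a deterministic SMO
solver (no randomized working-set choices), so training is reproducible
bit-for-bit. Voting ties break toward the class with the larger aggregate
decision margin.

`loso_evaluate()` implements leave-one-subject-out: one fold per subject,
with standardization *and* feature selection refit on each training split
— the leak-free reading. A `paper_mode` flag reproduces the alternative
single global selection. `cross_dataset_evaluate()` trains on one cohort
and tests on another, rejecting test labels unseen in training (the
second cohort legitimately lacks RUN). Reports carry per-fold accuracies,
their mean and standard deviation, the pooled row-normalized confusion
matrix, and per-class sensitivity/specificity; empty classes yield `NA`,
never a silent 0.

## The synthetic world

No recorded cohort is distributed, so every stage is exercised on a
generator whose defaults *are* the stated experimental conditions:
9 subjects, ~200 cycles each across WK/SA/SD/RUN separated by standing
rests, 5 s standing lead-in, 100 Hz.

`g_z` is rendered as half-cosine arcs between knots placed at the
annotated events: foot-off dip at the cycle start, swing peak at 25% of
the cycle, a 300 ms terminal-swing reversal into the foot-strike dip, a
stance rise to a small pre-swing hump (≈1.2–1.3 rad/s), and a 130 ms
plunge into the next foot-off dip. Negative dips additionally carry a
narrow triangular impact notch (±50 ms, 25% of the lobe) emulating the
impulsive character of ground contact and toe-off. Every intended
extremum sits exactly on a knot at a known sample, so annotations are
exact by construction.

Default profile parameters (generator conventions, not measurements):
swing-peak means 4.5/3.5/4.0/7.0 rad/s and cycle durations
1.1/1.4/1.2/0.75 s for WK/SA/SD/RUN, gyroscope noise sd 0.08 rad/s,
acceleration noise sd 0.4 m/s². Acceleration channels are phase-locked
harmonic waveforms with activity-specific amplitude vectors plus a strike
impact bump; subjects get lognormal jitter on durations, peaks and
amplitudes, and a small random constant mounting bias (the gyro component
clamped to ±0.04 rad/s, inside the detector's constant-bias robustness
envelope).

Two morphology choices deserve justification because they were driven by
the detector's own rules:

* **Margins.** The template satisfies the foot-off conjunction with ≥20 ms
  to spare (130 ms hump-to-dip against the 60 ms rule; ≥220 ms
  strike-to-hump against the 70 ms rule), and the stance rise is kept
  short and steep so the only signal stretches whose slope is comparable
  to the noise lie inside windows the rules already ignore. Without such
  margins a miss could be an artifact of the construction rather than of
  noise, and the detection criterion would be meaningless.
* **Bout initiation and termination.** An event-based detector cannot
  close a cycle before the first swing of a bout, so each bout renders a
  non-annotated gait-initiation stride (a first swing rising out of
  standing, preceded by a small counter-rotation dip) before the
  annotated cycles, and a terminal toe-off dip with a sub-threshold
  recovery swing after them. Every annotated cycle therefore has both
  boundary foot-offs physically present — mirroring experimental
  accounting in which bout-initiation strides are not labeled as cycles.

What the generator does *not* emulate: biomechanically validated waveform
shapes, slopes and turning, soft-tissue artifacts, sensor drift or
temperature effects, pathological gait. A green detection or
classification test therefore establishes that the chain implements its
rules correctly and robustly at realistic signal-to-noise ratios — not
that it would reach the same numbers on arbitrary clinical data.

## The six-configuration comparison

`run_comparison()` executes the factorial of pre-processing settings on
identical inputs and folds: (1) raw; (2) inclination-corrected; (3) raw
segmentation with post-hoc filtering of the segmented windows; (4)
inclination plus segment filtering; (5) whole-signal filtering; (6)
inclination plus filtering. Configurations 1/3 and 2/4 share event lists
by construction. Segment-window filtering resets filter state per window
(windows are independent post-hoc objects; no carryover rule exists to
mirror) and filters all six channels, since features consume all of them.
A cycle counts as detected when both boundary foot-offs fall within
±40 ms of annotation — deliberately stricter than the 50–135 ms
localization differences reported for comparable detectors, so the rate
is meaningful. Reports are serialized as timestamp-free JSON, so
identical runs are byte-identical.

## Numerical choices and degenerate inputs

* Sample indices are 0-based with half-open segments; `time = index/fs`.
* CSV numerics are written with 17 significant digits (lossless round
  trip); the sampling rate comes from a `# sampling_rate:` header when
  present, else the median time step; disagreement beyond 0.1% raises.
* The filter design asserts unity DC gain to 1e−9 and pole moduli < 1.
* The gap rules compare `(index difference)/fs` against the thresholds
  with a 1e−12 slack to keep integer-sample gaps exact.
* SMO uses tolerance 1e−3 and a deterministic second-choice heuristic;
  dual coefficients below 1e−8 are dropped from the support set.
* Constant feature columns standardize to zero (not NaN) and thus carry
  zero ranking weight.

## Known limitations

* The detector assumes the stereotyped positive-swing morphology of
  shank-mounted sagittal gyroscopes; other sensor placements need
  re-tuned thresholds.
* Foot-strike localization is the first confirmed minimum after the
  swing, which under heavy noise can fire early on the descent; foot-off
  localization (the quantity the cycle boundaries depend on) is protected
  by the rule conjunction, foot strike is not.
* The thresholds are implemented in rad/s exactly as published, including
  a gyroscope range stated in rad/s whose named hardware part is actually
  specified in degrees/s; the package takes no position on that
  discrepancy.
* `run_comparison()` at the default cohort size is minutes of CPU; the
  test suite runs it on a reduced cohort and the acceptance script runs
  only the raw configuration.
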