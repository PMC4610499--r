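# gaitseg

Event-based gait segmentation and physical-activity classification from a
single shank-mounted inertial measurement unit (IMU), for researchers and
engineers building real-time locomotion monitoring: the package answers
*where each gait cycle is* and *which activity it belongs to* — and how
little pre-processing those answers actually need.

## What it implements

Given six channels sampled at 100 Hz (tri-axial acceleration in m/s²,
tri-axial angular velocity in rad/s), the chain is:

1. **Pre-processing (optional).** Inclination correction subtracts the
   per-channel mean of an initial 5 s standing window. De-noising uses a
   causal IIR low-pass, `y_n = Σ_{k=0..M} b_k x_{n−k} − Σ_{k=1..N} a_k y_{n−k}`
   with N = M = 2 (the square of a pre-warped bilinear first-order
   section, 10 Hz cutoff, −15.6 dB at 20 Hz), usable sample-by-sample
   with carried state.
2. **Streaming segmentation.** A constant-memory automaton on the
   sagittal angular velocity `g_z`: a swing is accepted when the positive
   lobe between a rising and a falling zero crossing peaks above
   1.8 rad/s (mid-swing = argmax); the foot strike is the next confirmed
   local minimum; the foot-off is the local minimum `t_min` satisfying
   `t_min − t_max ≥ 60 ms  ∧  g_z(t_min) ≤ 1.4 rad/s  ∧  t_max − t_fs ≥ 70 ms`,
   with a 1.3 s timeout that discards the pending swing. A gait cycle is
   the span between consecutive foot-offs.
3. **Features.** 152 per-cycle descriptors over ax, ay, az, gx, gy, gz
   and the two orientation-independent magnitudes
   (`a_mag = √(ax²+ay²+az²)`): six time statistics, all ordered-pair
   correlations, spectral energy and DFT magnitudes 1–5.
4. **Classification.** One-vs-one soft-margin SVM (polynomial kernel,
   degree 1, complexity 1; deterministic SMO solver), features ranked by
   summed squared linear-SVM weights with the top 20 kept, evaluated by
   leave-one-subject-out (LOSO) or train-on-one-cohort/test-on-another.
5. **Comparison harness.** Six pre-processing configurations (raw;
   inclination; raw + segment filtering; inclination + segment filtering;
   filtered; inclination + filtered) run on identical folds, reporting
   accuracy, confusion, per-class sensitivity/specificity and
   cycle-detection rate against ground truth.

A synthetic gait generator (`generate_cohort()`) renders labeled
shank-IMU sessions — walking, stair ascent/descent, running, standing
rests — with sample-exact event annotations, so the whole chain is
testable without recorded data.

## Worked example

```r
library(gaitseg)

sim <- generate_session(default_protocol(10), seed = 42, subject_id = "demo")
rec <- sim$recording                  # imu_recording, 100 Hz, labeled

ev <- detect_events(rec$gz, detector_config())
head(ev, 5)
#>    event_type sample_index time_s     value
#> 1   MID_SWING          531   5.31  4.213640
#> 2 FOOT_STRIKE          557   5.57 -3.830888
#> 3    FOOT_OFF          614   6.14 -2.325912
#> 4   MID_SWING          642   6.42  4.958264
#> 5 FOOT_STRIKE          672   6.72 -3.614083
```

The first swing is found 5.3 s in (after the standing lead-in); foot-off
at sample 614 closes the first stride, at `g_z = −2.3` rad/s — below the
1.4 rad/s rule threshold as required.

```r
cyc <- cycles_from_events(ev, rec)
detection_rate(ev, sim$annotation)$rate
#> [1] 100                               # all 40 annotated cycles, ±40 ms

cyc <- cyc[cyc$activity_label %in% LOCOMOTION_LABELS, ]
cf <- extract_cycle_features(rec, cyc)  # 152 named features per cycle
rk <- rank_features_svm(cf$features, cf$meta$label)
head(rk, 3)
#>          name       score
#> 1 median_amag 0.005005537
#> 2     fft3_az 0.004646422
#> 3      iqr_az 0.004615193

frequency_response(design_lowpass(10, 100, 2), 20)
#> [1] -15.56303                         # dB at twice the corner frequency
```

On the full 9-subject synthetic cohort (seed 42, ~200 cycles/subject) the
raw-signal detector recovers 99.7% of annotated cycles within ±40 ms and
LOSO classification with top-20 features averages 99.9% accuracy — the
synthetic stand-ins for the published >99% detection / >98% accuracy
claims. Those numbers are recomputed, not asserted, by the acceptance
script below.

## Command line

```sh
Rscript inst/cli/gaitseg.R simulate --out-dir data/ --subjects 9 --seed 42
Rscript inst/cli/gaitseg.R segment  --input data/S01.csv --events-out events.csv --cycles-out cycles.csv
Rscript inst/cli/gaitseg.R features --input data/S01.csv --cycles cycles.csv --out features.csv
Rscript inst/cli/gaitseg.R compare  --data-dir data/ --report comparison.json --seed 42
```

Config files (detector thresholds, SVM spec, filter design) are JSON
mirroring the constructor arguments; see `vignettes/gaitseg-methods.Rmd`
for the model, its assumptions, every tunable parameter, and the design
decisions behind the synthetic world.
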