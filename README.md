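# visuomotor

Eye-hand coordination analysis for multimodal reach-to-grasp recordings.

When people grasp and manipulate objects, their eyes fixate the target
well before the hand arrives. Quantifying that anticipation — the window
between the first fixation on an object and the grasp, and the ordering
of eye, head, arm and muscle onsets — is central to movement neuroscience
and to gaze-informed control of upper-limb prostheses, where that window
is when gaze can inform intent recognition. This package implements a
complete, tested pipeline for such analyses on recordings combining
wearable eye tracking (100 Hz gaze, 25 fps scene video with per-frame
instance segmentations, head gyroscope), forearm accelerometry (148 Hz)
and two-channel surface EMG (1926 Hz), for able-bodied subjects and
transradial amputees executing grasps with their missing limb.

The pipeline's stages, each exposed as ordinary functions:

* **Gaze kinematics** — pupil-centred re-referencing
  (ĝᵢ = gᵢ − p̄ᵢ), angular differences
  αᵢ = arccos(ĝᵢ·ĝᵢ₋₁ / ‖ĝᵢ‖‖ĝᵢ₋₁‖) and velocities vᵢ = αᵢ/(tᵢ−tᵢ₋₁)
  in deg/s, with linear interpolation of pupil gaps shorter than 0.075 s.
* **Mask geometry** — minimum pixel distances between the gaze point, the
  target-object mask and the limb ("person") mask, measured to mask
  *contours* (0 on overlap), with the published instance-selection rules
  (score ≥ 0.8, largest area, lower-half person).
* **Signal conditioning** — 57-sample moving-RMS sEMG envelopes, rest
  baselines from [−2, −1) s before stimulus end, rest-referenced
  acceleration deviations, and resampling of everything onto a 20 ms
  analysis grid over [−2, 2.5] s.
* **Event detection** — fixation (< 20 px), saccade (last bin < 70 deg/s
  before fixation, starting ≥ 100 px away), head (> 12 deg/s), arm
  (> 0.07 g), muscles (> 4× baseline, either channel), grasp (< 5 px);
  two successive bins required, events in the first 100 ms invalidated.
* **Cohort statistics** — five event-pair intervals, type-7 quartiles,
  per-subject-mean Kolmogorov–Smirnov group comparisons, engagement rate,
  and time-locked median ± IQR modality profiles.
* **Synthetic trials** — a generator producing every stream with a
  *planted* event schedule (quartile-calibrated shifted log-normal
  latencies, pinhole-consistent gaze, rasterized masks, onset bursts),
  providing ground truth for validating every stage.

## Worked example

```r
library(visuomotor)

# one noiseless trial with a known schedule, end to end
profile <- noiseless_profile(intact_profile())
trial <- generate_trial(profile, desk_scene(), seed = 7)
round(trial$schedule$times, 3)
#> saccade fixation     head      arm  muscles    grasp
#>  -0.123    0.066   -0.481   -0.208   -0.247    0.466

detect_events(trial)
#>      event  time   status
#> 1 fixation  0.07 detected
#> 2  saccade -0.13 detected
#> 3     head -0.47 detected
#> 4      arm -0.19 detected
#> 5  muscles -0.23 detected
#> 6    grasp  0.47 detected
```

Every planted event is recovered within one 20 ms grid bin: the fixation
at 0.07 s versus 0.066 s planted, the grasp at 0.47 s versus 0.466 s,
and so on. At cohort scale (`run_pipeline(30, 14, 40, desk_scene(),
seed = 1)`, ~1,760 trials, a few minutes on one CPU) the pooled detected
intervals land on the calibrated group timing: the intact median
fixation→grasp interval comes out at 560 ms — the eyes lead the grasp by
over half a second in both groups — with head→arm 140 ms, arm→muscles
80 ms, and 95.6 % of trials engaging the target (the planted low-accuracy
fraction is 4.1 %).

The numbered scripts under `analysis/` run the same stages as a narrated
workflow: `01_simulate.R` writes a small cohort in the documented on-disk
layout, `02_distances_events.R` re-reads it and compares detected against
planted events, `03_interval_statistics.R` produces the per-interval
quartile/KS report at full cohort scale, and `04_profiles.R` the
time-locked median ± IQR profiles (tables under `results/`).

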