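Package: visuomotor
Title: Eye-Hand Coordination Analysis for Multimodal Reach-to-Grasp Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multimodal recordings of reach-to-grasp
    trials recorded with wearable eye tracking, head gyroscopes, forearm
    accelerometry and surface electromyography. Implements angular gaze
    kinematics with short-gap pupil interpolation, contour-based pixel
    distances between the gaze point, target-object and limb segmentation
    masks, threshold-based detection of six visuomotor events (saccade,
    fixation, head, arm, muscle and grasp onsets) on a common 20 ms analysis
    grid, and cohort-level interval statistics including quartile summaries,
    per-subject Kolmogorov-Smirnov group comparisons, engagement rates and
    time-locked median profiles. A synthetic multimodal trial generator with
    a planted event schedule provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
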