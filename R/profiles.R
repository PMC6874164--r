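#' Timing profiles describing a simulated subject group
#'
#' A timing profile collects the latency distributions and noise levels that
#' drive the synthetic trial generator. Event times are built relative to
#' the end of the vocal instruction (time 0) as
#'
#' * `saccade  = saccade_onset`
#' * `fixation = saccade + saccade_to_fixation`
#' * `head     = saccade + saccade_to_head`
#' * `arm      = head + head_to_arm`
#' * `muscles  = arm + arm_to_muscles`
#' * `grasp    = fixation + fixation_to_grasp` (absent when the limb does
#'   not visually reach the target)
#'
#' The packaged group profiles [intact_profile()] and [amputated_profile()]
#' calibrate the interval distributions to the published per-group quartile
#' triplets via [dist_quartile_lognormal()], so the planted pooled medians
#' equal the printed ones (561/160/20/120/80 ms for intact subjects;
#' 1042/140/-20/140/581 ms for amputated subjects).
#'
#' @param group `"intact"` or `"amputated"`.
#' @param saccade_onset,saccade_to_fixation,saccade_to_head,head_to_arm,arm_to_muscles,fixation_to_grasp
#'   [`vm_dist`][latency-distributions] objects (seconds).
#' @param gaze_noise_deg sd of the sample-to-sample gaze jitter (degrees of
#'   visual angle; temporally smoothed).
#' @param gaze_accuracy_deg sd of the per-trial systematic gaze offset
#'   (degrees); models calibration accuracy.
#' @param low_accuracy_fraction fraction of trials whose systematic offset
#'   exceeds the fixation distance threshold, so the gaze never comes within
#'   20 px of the target mask. Default 0.041 reproduces a 95.9 % engagement
#'   rate.
#' @param low_accuracy_margin_px `c(min, max)` uniform range of the extra
#'   offset (beyond threshold + target radius) used for low-accuracy trials.
#' @param touch_fraction fraction of trials in which the limb mask visually
#'   reaches the target (grasp event exists). 1 for intact subjects; 0.45
#'   for amputated subjects, matching the published ratio of grasp counts
#'   to trials.
#' @param stop_short_px distribution of the subject-specific stop-short
#'   offset (px) for non-touching trials.
#' @param subject_onset_sd,subject_interval_sd sd (s) of the per-subject
#'   random shift of the saccade onset and of each event-pair latency.
#' @param dropout_rate expected number of pupil dropout gaps per second;
#'   `dropout_short_frac` of them are 1-6 samples long (interpolatable at
#'   100 Hz under the 0.075 s rule), the rest 8-16 samples.
#' @param gyro_noise,acc_noise per-axis rest noise sd (deg/s, g).
#' @param gyro_peak,gyro_burst_s head angular-velocity burst peak (deg/s)
#'   and duration (s).
#' @param acc_step,acc_peak,acc_rise_s acceleration deviation plateau (g),
#'   additional reach peak (g) and rise time (s).
#' @param emg_noise_sd per-channel sEMG baseline amplitude ("mV", arbitrary
#'   units); `emg_stochastic = FALSE` replaces the stochastic carrier by a
#'   deterministic 150 Hz sinusoid with the same RMS so that noiseless
#'   fixtures retain a positive baseline.
#' @param emg_gain_ext,emg_gain_flex activation gains (multiples of
#'   baseline) for the extensor and flexor bursts; the flexor burst starts
#'   `emg_flexor_lag_s` after the muscle onset so the extensor leads.
#' @return A `vm_profile` list.
#' @seealso [sample_schedule()], [generate_trial()]
#' @export
timing_profile <- function(group = c("intact", "amputated"),
                           saccade_onset = dist_normal(-0.25, 0.10),
                           saccade_to_fixation = dist_quartile_lognormal_ordered(0.080, 0.160, 0.301),
                           saccade_to_head = dist_quartile_lognormal(-0.301, 0.020, 0.160),
                           head_to_arm = dist_quartile_lognormal(0.020, 0.120, 0.301),
                           arm_to_muscles = dist_quartile_lognormal(-0.020, 0.080, 0.401),
                           fixation_to_grasp = dist_quartile_lognormal_ordered(0.321, 0.561, 0.842),
                           gaze_noise_deg = 0.15,
                           gaze_accuracy_deg = 0.30,
                           low_accuracy_fraction = 0.041,
                           low_accuracy_margin_px = c(15, 45),
                           touch_fraction = 1,
                           stop_short_px = dist_quartile_lognormal(25, 40, 65),
                           subject_onset_sd = 0.05,
                           subject_interval_sd = 0.04,
                           dropout_rate = 0.4,
                           dropout_short_frac = 0.7,
                           gyro_noise = 2,
                           acc_noise = 0.01,
                           gyro_peak = 60,
                           gyro_burst_s = 1.5,
                           acc_step = 0.10,
                           acc_peak = 0.25,
                           acc_rise_s = 0.8,
                           emg_noise_sd = c(0.015, 0.012),
                           emg_stochastic = TRUE,
                           emg_gain_ext = c(5.5, 9),
                           emg_gain_flex = c(5, 9),
                           emg_flexor_lag_s = 0.15) {
  group <- match.arg(group)
  dists <- list(saccade_onset = saccade_onset,
                saccade_to_fixation = saccade_to_fixation,
                saccade_to_head = saccade_to_head,
                head_to_arm = head_to_arm,
                arm_to_muscles = arm_to_muscles,
                fixation_to_grasp = fixation_to_grasp,
                stop_short_px = stop_short_px)
  ok <- vapply(dists, inherits, logical(1), what = "vm_dist")
  if (!all(ok)) {
    stop("latency arguments must be vm_dist objects: ",
         paste(names(dists)[!ok], collapse = ", "), call. = FALSE)
  }
  fracs <- c(low_accuracy_fraction = low_accuracy_fraction,
             touch_fraction = touch_fraction,
             dropout_short_frac = dropout_short_frac)
  if (any(fracs < 0 | fracs > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(gaze_noise_deg >= 0, gaze_accuracy_deg >= 0,
            subject_onset_sd >= 0, subject_interval_sd >= 0,
            dropout_rate >= 0, gyro_noise >= 0, acc_noise >= 0,
            gyro_peak > 12, acc_step > 0.07,
            length(emg_noise_sd) == 2L, all(emg_noise_sd > 0),
            length(low_accuracy_margin_px) == 2L,
            low_accuracy_margin_px[1] > 0,
            diff(low_accuracy_margin_px) >= 0)
  structure(
    c(list(group = group), dists,
      list(gaze_noise_deg = gaze_noise_deg,
           gaze_accuracy_deg = gaze_accuracy_deg,
           low_accuracy_fraction = low_accuracy_fraction,
           low_accuracy_margin_px = low_accuracy_margin_px,
           touch_fraction = touch_fraction,
           subject_onset_sd = subject_onset_sd,
           subject_interval_sd = subject_interval_sd,
           dropout_rate = dropout_rate,
           dropout_short_frac = dropout_short_frac,
           gyro_noise = gyro_noise, acc_noise = acc_noise,
           gyro_peak = gyro_peak, gyro_burst_s = gyro_burst_s,
           acc_step = acc_step, acc_peak = acc_peak,
           acc_rise_s = acc_rise_s,
           emg_noise_sd = emg_noise_sd,
           emg_stochastic = emg_stochastic,
           emg_gain_ext = emg_gain_ext,
           emg_gain_flex = emg_gain_flex,
           emg_flexor_lag_s = emg_flexor_lag_s)),
    class = "vm_profile"
  )
}

#' Packaged group profiles
#'
#' `intact_profile()` and `amputated_profile()` return the default timing
#' profiles for the able-bodied and transradial-amputee groups, with the
#' interval distributions quartile-calibrated to the published per-group
#' triplets (seconds): see [timing_profile()] for the construction.
#' `noiseless_profile()` strips all stochastic components from a profile
#' (zero gaze/gyro/acc noise, no dropouts, no systematic offsets, a
#' deterministic sEMG carrier), which is useful for exact planted-event
#' recovery fixtures.
#'
#' @param ... overrides forwarded to [timing_profile()].
#' @export
intact_profile <- function(...) {
  timing_profile(group = "intact", ...)
}

#' @rdname intact_profile
#' @export
amputated_profile <- function(...) {
  timing_profile(
    group = "amputated",
    saccade_to_fixation = dist_quartile_lognormal_ordered(0.060, 0.140, 0.281),
    saccade_to_head = dist_quartile_lognormal(-0.461, -0.020, 0.140),
    head_to_arm = dist_quartile_lognormal(0.000, 0.140, 0.371),
    arm_to_muscles = dist_quartile_lognormal(0.200, 0.581, 1.042),
    fixation_to_grasp = dist_quartile_lognormal_ordered(0.581, 1.042, 1.644),
    touch_fraction = 0.45,
    ...
  )
}

#' @rdname intact_profile
#' @param base profile to strip.
#' @export
noiseless_profile <- function(base = intact_profile()) {
  stopifnot(inherits(base, "vm_profile"))
  base$gaze_noise_deg <- 0
  base$gaze_accuracy_deg <- 0
  base$low_accuracy_fraction <- 0
  base$subject_onset_sd <- 0
  base$subject_interval_sd <- 0
  base$dropout_rate <- 0
  base$gyro_noise <- 0
  base$acc_noise <- 0
  base$emg_stochastic <- FALSE
  base
}

#' @export
print.vm_profile <- function(x, ...) {
  cat(sprintf("<vm_profile: %s>\n", x$group))
  for (nm in c("saccade_to_fixation", "saccade_to_head", "head_to_arm",
               "arm_to_muscles", "fixation_to_grasp")) {
    q <- signif(dist_quartiles(x[[nm]]), 3)
    cat(sprintf("  %-20s Q1=%g med=%g Q3=%g s\n", nm, q[1], q[2], q[3]))
  }
  cat(sprintf("  touch fraction %.2f, low-accuracy fraction %.3f\n",
              x$touch_fraction, x$low_accuracy_fraction))
  invisible(x)
}
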