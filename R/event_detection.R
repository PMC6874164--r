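#' Detection configuration
#'
#' Thresholds and windowing for the six visuomotor events. Defaults equal
#' the published values: fixation when the gaze-target distance is < 20 px
#' for two successive 20 ms samples; saccade onset at the last sample with
#' gaze velocity < 70 deg/s within 500 ms before the fixation, required to
#' start from a gaze-target distance of at least 100 px; head onset when
#' the gyroscope norm exceeds 12 deg/s; arm onset when the rest-referenced
#' acceleration deviation norm exceeds 0.07 g; muscle onset when either
#' sEMG envelope exceeds 4x its rest baseline; grasp when the limb-target
#' distance is < 5 px. All rules run on the 20 ms analysis grid over
#' [-2, 2.5] s around the stimulus end, and any event found within the
#' first 100 ms of the window is invalidated (the subject was not at rest
#' or was already fixating the target).
#'
#' @param fixation_px,saccade_deg_s,saccade_lookback_s,saccade_min_start_px,head_deg_s,arm_g,muscle_multiplier,grasp_px
#'   event thresholds (strict inequalities, as printed).
#' @param successive number of successive grid samples required.
#' @param window analysis window (s relative to stimulus end).
#' @param early_invalid_s span at the start of the window in which detected
#'   events are invalidated.
#' @param grid_step analysis resolution (s).
#' @return A `vm_detection_config` list.
#' @export
detection_config <- function(fixation_px = 20, saccade_deg_s = 70,
                             saccade_lookback_s = 0.5,
                             saccade_min_start_px = 100,
                             head_deg_s = 12, arm_g = 0.07,
                             muscle_multiplier = 4, grasp_px = 5,
                             successive = 2L, window = c(-2, 2.5),
                             early_invalid_s = 0.1, grid_step = 0.02) {
  thr <- c(fixation_px, saccade_deg_s, saccade_lookback_s,
           saccade_min_start_px, head_deg_s, arm_g, muscle_multiplier,
           grasp_px, early_invalid_s, grid_step)
  if (any(!is.finite(thr)) || any(thr <= 0)) {
    stop("all thresholds must be positive", call. = FALSE)
  }
  stopifnot(length(window) == 2L, window[1] < window[2], successive >= 1)
  structure(list(fixation_px = fixation_px, saccade_deg_s = saccade_deg_s,
                 saccade_lookback_s = saccade_lookback_s,
                 saccade_min_start_px = saccade_min_start_px,
                 head_deg_s = head_deg_s, arm_g = arm_g,
                 muscle_multiplier = muscle_multiplier, grasp_px = grasp_px,
                 successive = as.integer(successive), window = window,
                 early_invalid_s = early_invalid_s, grid_step = grid_step),
            class = "vm_detection_config")
}

#' First sustained threshold crossing on the analysis grid
#'
#' Time of the first grid bin starting a run of at least `k` consecutive
#' non-missing bins below (`first_sustained_below()`) or strictly above
#' (`first_sustained_above()`) the threshold. Missing bins break runs, so
#' single-bin outliers straddled by missing data never trigger.
#'
#' @param time grid bin centres.
#' @param x gridded values (`NA` = missing).
#' @param threshold threshold (strict comparison).
#' @param k run length required.
#' @return The bin time, or `NA` if no such run exists.
#' @export
first_sustained_below <- function(time, x, threshold, k = 2L) {
  first_sustained(time, !is.na(x) & x < threshold, k)
}

#' @rdname first_sustained_below
#' @export
first_sustained_above <- function(time, x, threshold, k = 2L) {
  first_sustained(time, !is.na(x) & x > threshold, k)
}

first_sustained <- function(time, ok, k) {
  if (!any(ok)) return(NA_real_)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= k)
  if (!length(hit)) return(NA_real_)
  time[ends[hit[1]] - r$lengths[hit[1]] + 1L]
}

event_result <- function(time, cfg) {
  if (is.na(time)) {
    list(time = NA_real_, status = "missing")
  } else if (time < cfg$window[1] + cfg$early_invalid_s) {
    list(time = NA_real_, status = "invalid_early")
  } else {
    list(time = time, status = "detected")
  }
}

undetectable <- function() list(time = NA_real_, status = "undetectable")

#' Individual event detectors
#'
#' Each detector takes gridded series (bin centres `time` plus values) and
#' a [detection_config()], and returns a list with `time` (s, `NA` unless
#' detected) and `status` (`"detected"`, `"missing"`, `"invalid_early"` or
#' `"undetectable"`).
#'
#' `detect_saccade()` scans backwards from the detected fixation over the
#' lookback span for the latest non-missing velocity bin below the saccade
#' velocity threshold, and requires the gaze-target distance at that bin to
#' be at least `saccade_min_start_px`; missing velocity bins inside the
#' saccadic burst therefore do not displace the onset.
#'
#' @param time grid bin centres.
#' @param gaze_target,velocity,gyro_norm,acc_norm gridded series.
#' @param envelopes list with gridded `extensor` and `flexor` envelopes.
#' @param baselines named vector from [emg_baseline()].
#' @param fixation result of `detect_fixation()`.
#' @param cfg a [detection_config()].
#' @name event-detectors
NULL

#' @rdname event-detectors
#' @export
detect_fixation <- function(time, gaze_target, cfg = detection_config()) {
  event_result(first_sustained_below(time, gaze_target, cfg$fixation_px,
                                     cfg$successive), cfg)
}

#' @rdname event-detectors
#' @export
detect_saccade <- function(time, velocity, gaze_target, fixation,
                           cfg = detection_config()) {
  if (fixation$status != "detected") {
    return(list(time = NA_real_, status = "missing"))
  }
  tf <- fixation$time
  sel <- which(time < tf - 1e-9 & time >= tf - cfg$saccade_lookback_s - 1e-9)
  if (!length(sel)) return(list(time = NA_real_, status = "missing"))
  sub <- sel[!is.na(velocity[sel]) & velocity[sel] < cfg$saccade_deg_s]
  if (!length(sub)) return(list(time = NA_real_, status = "missing"))
  i <- sub[length(sub)]
  d <- gaze_target[i]
  if (is.na(d) || d < cfg$saccade_min_start_px) {
    return(list(time = NA_real_, status = "missing"))
  }
  event_result(time[i], cfg)
}

#' @rdname event-detectors
#' @export
detect_head <- function(time, gyro_norm, cfg = detection_config()) {
  event_result(first_sustained_above(time, gyro_norm, cfg$head_deg_s,
                                     cfg$successive), cfg)
}

#' @rdname event-detectors
#' @export
detect_arm <- function(time, acc_norm, cfg = detection_config()) {
  event_result(first_sustained_above(time, acc_norm, cfg$arm_g,
                                     cfg$successive), cfg)
}

#' @rdname event-detectors
#' @export
detect_muscles <- function(time, envelopes, baselines,
                           cfg = detection_config()) {
  if (is.null(baselines)) return(undetectable())
  # the either-channel comparison is per bin
  over <- (!is.na(envelopes$extensor) &
             envelopes$extensor > cfg$muscle_multiplier * baselines[["extensor"]]) |
          (!is.na(envelopes$flexor) &
             envelopes$flexor > cfg$muscle_multiplier * baselines[["flexor"]])
  event_result(first_sustained(time, over, cfg$successive), cfg)
}

#' @rdname event-detectors
#' @export
detect_grasp <- function(time, limb_target, cfg = detection_config()) {
  event_result(first_sustained_below(time, limb_target, cfg$grasp_px,
                                     cfg$successive), cfg)
}

#' Gridded per-trial features
#'
#' Conditions every modality of a trial and resamples it onto the 20 ms
#' analysis grid: angular gaze velocity (computed at the native gaze rate
#' after short-gap pupil interpolation, then bin-averaged), the three
#' frame-rate pixel distances (nearest frame within one grid step),
#' gyroscope norm, rest-referenced acceleration deviation norm and the two
#' sEMG envelopes (bin means), plus the per-channel rest baselines.
#'
#' @param trial a [`vm_trial`][generate_trial].
#' @param cfg a [detection_config()].
#' @return List with `time` (bin centres), the gridded series, `baselines`,
#'   and `min_gaze_target` (trial-wide minimum gaze-target distance at the
#'   native frame rate, used for engagement).
#' @export
trial_features <- function(trial, cfg = detection_config()) {
  grid <- analysis_grid(cfg$window, cfg$grid_step)
  st <- cfg$grid_step
  feats <- list(time = grid)

  if (!is.null(trial$frames)) {
    ds <- distance_series(trial)
    for (nm in c("gaze_target", "gaze_limb", "limb_target")) {
      feats[[nm]] <- resample_to_grid(ds$t, ds[[nm]], grid,
                                      method = "nearest", step = st,
                                      tol = st)
    }
    feats$min_gaze_target <- if (all(is.na(ds$gaze_target))) NA_real_ else
      min(ds$gaze_target, na.rm = TRUE)
  }
  if (!is.null(trial$gaze)) {
    vel <- gaze_velocity(interpolate_pupils(trial$gaze))
    feats$velocity <- resample_to_grid(vel$t, vel$velocity, grid, step = st)
  }
  if (!is.null(trial$gyro)) {
    gn <- row_norm(cbind(trial$gyro$x, trial$gyro$y, trial$gyro$z))
    feats$gyro_norm <- resample_to_grid(trial$gyro$t, gn, grid, step = st)
  }
  if (!is.null(trial$acc)) {
    na <- normalize_acc(trial$acc, trial$meta$stimulus_end %||% 0)
    if (!is.null(na)) {
      feats$acc_norm <- resample_to_grid(na$deviation$t, na$deviation$norm,
                                         grid, step = st)
    }
  }
  if (!is.null(trial$emg)) {
    env <- emg_envelope(trial$emg)
    feats$baselines <- emg_baseline(env, trial$meta$stimulus_end %||% 0)
    feats$ext_env <- resample_to_grid(env$t, env$extensor, grid, step = st)
    feats$flex_env <- resample_to_grid(env$t, env$flexor, grid, step = st)
  }
  feats
}

#' Detect the six visuomotor events of a trial
#'
#' Runs all six detectors on the trial's gridded features. Events whose
#' required stream is absent are marked `"undetectable"`; events found in
#' the first 100 ms of the analysis window are `"invalid_early"`; events
#' whose conditions are never met are `"missing"`.
#'
#' @inheritParams trial_features
#' @param features optionally precomputed [trial_features()].
#' @return A `vm_events` data frame with one row per event (`event`,
#'   `time`, `status`).
#' @export
detect_events <- function(trial, cfg = detection_config(),
                          features = NULL) {
  f <- features %||% trial_features(trial, cfg)
  tm <- f$time

  fixation <- if (is.null(f$gaze_target)) undetectable() else
    detect_fixation(tm, f$gaze_target, cfg)
  saccade <- if (is.null(f$velocity) || is.null(f$gaze_target)) {
    undetectable()
  } else {
    detect_saccade(tm, f$velocity, f$gaze_target, fixation, cfg)
  }
  head <- if (is.null(f$gyro_norm)) undetectable() else
    detect_head(tm, f$gyro_norm, cfg)
  arm <- if (is.null(f$acc_norm)) undetectable() else
    detect_arm(tm, f$acc_norm, cfg)
  muscles <- if (is.null(f$ext_env)) undetectable() else
    detect_muscles(tm, list(extensor = f$ext_env, flexor = f$flex_env),
                   f$baselines, cfg)
  grasp <- if (is.null(f$limb_target)) undetectable() else
    detect_grasp(tm, f$limb_target, cfg)

  ev <- list(fixation = fixation, saccade = saccade, head = head,
             arm = arm, muscles = muscles, grasp = grasp)
  out <- data.frame(
    event = names(ev),
    time = vapply(ev, function(e) e$time, numeric(1)),
    status = vapply(ev, function(e) e$status, character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("vm_events", "data.frame")
  out
}
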