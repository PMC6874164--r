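#' Sample a planted event schedule
#'
#' Draws one trial's true event times (seconds relative to the end of the
#' vocal instruction) from a timing profile. Ordering constraints
#' (`saccade < fixation`, `fixation < grasp` when a grasp exists) and
#' containment of every event inside the usable part of the analysis window
#' are enforced by rejection resampling of the whole draw.
#'
#' @param profile a [`vm_profile`][timing_profile].
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @param effects optional per-subject random effects as produced by
#'   [sample_subject_effects()]; additive shifts on the saccade onset and on
#'   each event-pair latency, plus the subject's stop-short offset.
#' @param window analysis window (s) the events must fall into; events must
#'   also clear the first 100 ms of the window (the early-invalidation span)
#'   plus one grid step, and leave two grid steps before the window end so
#'   they remain detectable.
#' @param max_tries rejection-resampling budget before failing.
#' @return A `vm_schedule`: list with `times` (named vector `saccade`,
#'   `fixation`, `head`, `arm`, `muscles`, `grasp`; `grasp` is `NA` for
#'   non-touching trials), plus logical `touch` and `low_accuracy` flags.
#' @examples
#' p <- intact_profile()
#' sample_schedule(p, seed = 1)
#' @export
sample_schedule <- function(profile, seed = NULL, effects = NULL,
                            window = c(-2, 2.5), max_tries = 1000L) {
  stopifnot(inherits(profile, "vm_profile"))
  eff <- effects %||% list(onset = 0, saccade_to_fixation = 0,
                           saccade_to_head = 0, head_to_arm = 0,
                           arm_to_muscles = 0, fixation_to_grasp = 0,
                           stop_short_px = NA_real_)
  lo <- window[1] + 0.1 + 0.04   # clear early invalidation + one grid step
  hi <- window[2] - 0.04         # leave two 20 ms bins before the end
  with_seed(seed, {
    touch <- stats::runif(1) < profile$touch_fraction
    low_accuracy <- stats::runif(1) < profile$low_accuracy_fraction
    for (i in seq_len(max_tries)) {
      saccade <- sample_dist(profile$saccade_onset) + eff$onset
      fixation <- saccade + sample_dist(profile$saccade_to_fixation) +
        eff$saccade_to_fixation
      head <- saccade + sample_dist(profile$saccade_to_head) +
        eff$saccade_to_head
      arm <- head + sample_dist(profile$head_to_arm) + eff$head_to_arm
      muscles <- arm + sample_dist(profile$arm_to_muscles) +
        eff$arm_to_muscles
      grasp <- if (touch) {
        fixation + sample_dist(profile$fixation_to_grasp) +
          eff$fixation_to_grasp
      } else {
        NA_real_
      }
      times <- c(saccade = saccade, fixation = fixation, head = head,
                 arm = arm, muscles = muscles, grasp = grasp)
      present <- times[!is.na(times)]
      ok <- saccade < fixation &&
        (!touch || fixation < grasp) &&
        all(present > lo) && all(present < hi)
      if (ok) {
        return(structure(
          list(times = times, touch = touch, low_accuracy = low_accuracy,
               window = window,
               stop_short_px = eff$stop_short_px),
          class = "vm_schedule"
        ))
      }
    }
    stop(sprintf(paste0(
      "could not draw an ordered in-window schedule in %d tries; ",
      "check the saccade_to_fixation / fixation_to_grasp distributions ",
      "against the analysis window"), max_tries), call. = FALSE)
  })
}

#' Per-subject random effects
#'
#' Draws the subject-level shifts applied on top of a timing profile:
#' a shared shift of the saccade onset (`subject_onset_sd`), an additive
#' shift per event-pair latency (`subject_interval_sd`) and the subject's
#' stop-short pixel offset used for non-touching trials (a constant,
#' subject-dependent distance).
#'
#' @inheritParams sample_schedule
#' @return A named list of shifts (seconds) plus `stop_short_px`.
#' @export
sample_subject_effects <- function(profile, seed = NULL) {
  stopifnot(inherits(profile, "vm_profile"))
  with_seed(seed, {
    s <- profile$subject_interval_sd
    list(onset = stats::rnorm(1, 0, profile$subject_onset_sd),
         saccade_to_fixation = stats::rnorm(1, 0, s),
         saccade_to_head = stats::rnorm(1, 0, s),
         head_to_arm = stats::rnorm(1, 0, s),
         arm_to_muscles = stats::rnorm(1, 0, s),
         fixation_to_grasp = stats::rnorm(1, 0, s),
         stop_short_px = max(12, sample_dist(profile$stop_short_px)))
  })
}

#' @export
print.vm_schedule <- function(x, ...) {
  cat("<vm_schedule> (s relative to stimulus end)\n")
  print(round(x$times, 3))
  cat(sprintf("  touch: %s, low accuracy: %s\n", x$touch, x$low_accuracy))
  invisible(x)
}
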