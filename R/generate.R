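#' Generate a complete synthetic trial
#'
#' Draws a planted event schedule and synthesizes all modality streams for
#' one reach-to-grasp trial: gaze (with pinhole-consistent 3-D/2-D
#' representations), per-frame instance segmentations, head gyroscope,
#' forearm accelerometry and two-channel sEMG, plus trial metadata (target
#' object class, task type, vocal instruction).
#'
#' @inheritParams synth_gaze
#' @param effects optional per-subject effects from
#'   [sample_subject_effects()].
#' @param subject,trial_id identifiers stored in the trial metadata.
#' @param distractors forwarded to [synth_masks()].
#' @return A `vm_trial`: list with `meta`, `schedule`, `gaze`, `frames`,
#'   `gyro`, `acc`, `emg` and `scene`.
#' @examples
#' tr <- generate_trial(noiseless_profile(), desk_scene(), seed = 7)
#' tr$schedule
#' @export
generate_trial <- function(profile, scene = desk_scene(), seed = NULL,
                           effects = NULL, subject = "S01", trial_id = 1L,
                           distractors = FALSE) {
  stopifnot(inherits(profile, "vm_profile"), inherits(scene, "vm_scene"))
  with_seed(seed, {
    if (is.null(effects)) {
      effects <- list(onset = 0, saccade_to_fixation = 0, saccade_to_head = 0,
                      head_to_arm = 0, arm_to_muscles = 0,
                      fixation_to_grasp = 0,
                      stop_short_px = max(12, sample_dist(profile$stop_short_px)))
    }
    schedule <- sample_schedule(profile, effects = effects,
                                window = scene$window)
    task_type <- sample(c("static", "functional"), 1)
    if (task_type == "functional") {
      row <- vm_task_table[sample(nrow(vm_task_table), 1), ]
      instruction <- row$instruction
      target_class <- row$object
      position <- row$position
    } else {
      instruction <- NA_character_
      target_class <- sample(vm_object_classes, 1)
      position <- sample(c("seated", "standing"), 1)
    }
    trial <- list(
      meta = list(subject = subject, group = profile$group,
                  trial_id = trial_id, target_class = target_class,
                  task_type = task_type, instruction = instruction,
                  position = position, stimulus_end = 0),
      schedule = schedule,
      gaze = synth_gaze(schedule, scene, profile),
      frames = synth_masks(schedule, scene, profile,
                           target_class = target_class,
                           distractors = distractors),
      gyro = synth_gyro(schedule, scene, profile),
      acc = synth_acc(schedule, scene, profile),
      emg = synth_emg(schedule, scene, profile),
      scene = scene
    )
    class(trial) <- "vm_trial"
    trial
  })
}

#' Plan and generate a synthetic cohort
#'
#' `cohort_plan()` draws per-subject random effects and one RNG seed per
#' trial, so that any single trial can be regenerated independently (used
#' by the streaming analysis in [analyze_cohort()]). `generate_cohort()`
#' materializes all trials in memory; it is intended for small cohorts
#' (tests, examples), since each trial carries its full mask stack.
#'
#' @inheritParams generate_trial
#' @param n_subjects,trials_per_subject cohort dimensions; both must be
#'   positive.
#' @param seed integer seed making the whole cohort reproducible.
#' @return `cohort_plan()`: list with `table` (subject, trial, seed) and
#'   `effects` (per-subject random effects). `generate_cohort()`: a
#'   `vm_cohort` list with `trials`, `plan`, `profile` and `scene`.
#' @examples
#' coh <- generate_cohort(2, 3, noiseless_profile(), desk_scene(), seed = 1)
#' length(coh$trials)
#' @export
cohort_plan <- function(n_subjects, trials_per_subject, profile,
                        seed = NULL) {
  if (n_subjects <= 0 || trials_per_subject <= 0) {
    stop("n_subjects and trials_per_subject must be positive", call. = FALSE)
  }
  with_seed(seed, {
    subjects <- sprintf("%s%02d",
                        if (profile$group == "intact") "C" else "A",
                        seq_len(n_subjects))
    effects <- lapply(subjects, function(s) sample_subject_effects(profile))
    names(effects) <- subjects
    n <- n_subjects * trials_per_subject
    tab <- data.frame(
      subject = rep(subjects, each = trials_per_subject),
      trial = rep(seq_len(trials_per_subject), n_subjects),
      seed = sample.int(.Machine$integer.max, n),
      stringsAsFactors = FALSE
    )
    list(table = tab, effects = effects)
  })
}

#' @rdname cohort_plan
#' @export
generate_cohort <- function(n_subjects, trials_per_subject, profile,
                            scene = desk_scene(), seed = NULL) {
  plan <- cohort_plan(n_subjects, trials_per_subject, profile, seed)
  trials <- vector("list", nrow(plan$table))
  for (i in seq_len(nrow(plan$table))) {
    row <- plan$table[i, ]
    trials[[i]] <- generate_trial(profile, scene, seed = row$seed,
                                  effects = plan$effects[[row$subject]],
                                  subject = row$subject,
                                  trial_id = row$trial)
  }
  structure(list(trials = trials, plan = plan, profile = profile,
                 scene = scene),
            class = "vm_cohort")
}
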