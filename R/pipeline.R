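#' Analyze a single trial
#'
#' Runs the full per-trial pipeline: distance computation, signal
#' conditioning, gridding and event detection.
#'
#' @inheritParams trial_features
#' @param keep_features also return the gridded features.
#' @return List with `events` (a [`vm_events`][detect_events] frame
#'   augmented with trial metadata), `min_gaze_target`, and optionally
#'   `features`.
#' @export
analyze_trial <- function(trial, cfg = detection_config(),
                          keep_features = FALSE) {
  f <- trial_features(trial, cfg)
  ev <- detect_events(trial, cfg, features = f)
  ev$subject <- trial$meta$subject
  ev$group <- trial$meta$group
  ev$trial <- trial$meta$trial_id
  out <- list(events = ev, min_gaze_target = f$min_gaze_target %||% NA_real_)
  if (keep_features) out$features <- f
  out
}

#' Simulate and analyze a cohort, one trial at a time
#'
#' Generates each trial of a planned cohort, runs the per-trial analysis
#' and discards the raw streams before moving on, so arbitrarily large
#' cohorts run in bounded memory. Per-trial gridded modality profiles can
#' be retained for [profile_aggregate()].
#'
#' @inheritParams cohort_plan
#' @inheritParams generate_trial
#' @param cfg a [detection_config()].
#' @param keep_profiles character vector of gridded feature names to
#'   collect into trials-by-bins matrices (e.g.
#'   `c("gaze_target", "velocity")`), or `NULL`.
#' @param progress print a progress line every 200 trials.
#' @return List with `events` (long data frame over all trials),
#'   `intervals` ([compute_intervals()]), `min_gaze_target` (per trial),
#'   `schedules` (planted times per trial), `profiles` (named list of
#'   matrices, if requested) and `plan`.
#' @export
analyze_cohort <- function(n_subjects, trials_per_subject, profile,
                           scene = desk_scene(), cfg = detection_config(),
                           seed = NULL, keep_profiles = NULL,
                           progress = FALSE) {
  plan <- cohort_plan(n_subjects, trials_per_subject, profile, seed)
  tab <- plan$table
  n <- nrow(tab)
  grid <- analysis_grid(cfg$window, cfg$grid_step)
  ev_list <- vector("list", n)
  mins <- rep(NA_real_, n)
  sched <- vector("list", n)
  prof_mats <- if (!is.null(keep_profiles)) {
    stats::setNames(
      lapply(keep_profiles, function(x) matrix(NA_real_, n, length(grid))),
      keep_profiles
    )
  }
  for (i in seq_len(n)) {
    trial <- generate_trial(profile, scene, seed = tab$seed[i],
                            effects = plan$effects[[tab$subject[i]]],
                            subject = tab$subject[i],
                            trial_id = tab$trial[i])
    res <- analyze_trial(trial, cfg, keep_features = !is.null(keep_profiles))
    ev_list[[i]] <- res$events
    mins[i] <- res$min_gaze_target
    sched[[i]] <- trial$schedule$times
    if (!is.null(keep_profiles)) {
      for (nm in keep_profiles) {
        v <- res$features[[nm]]
        if (!is.null(v)) prof_mats[[nm]][i, ] <- v
      }
    }
    if (progress && i %% 200 == 0) {
      message(sprintf("  %d / %d trials", i, n))
    }
  }
  events <- do.call(rbind, ev_list)
  rownames(events) <- NULL
  schedules <- do.call(rbind, sched)
  schedules <- data.frame(subject = tab$subject, trial = tab$trial,
                          schedules, stringsAsFactors = FALSE)
  list(events = events, intervals = compute_intervals(events),
       min_gaze_target = mins, schedules = schedules,
       profiles = prof_mats, plan = plan, grid = grid)
}

#' Run the full simulate-then-analyze pipeline
#'
#' Orchestrates an end-to-end reproducible run: simulates an intact and an
#' amputated cohort, analyzes every trial, and writes the event table, the
#' interval table, the per-interval group report and the engagement rate
#' as tab-separated files (with a format-version header and the thresholds
#' echoed for provenance) under `out_dir`.
#'
#' @param n_intact,n_amputated subjects per group (0 skips a group).
#' @param trials_per_subject trials per subject.
#' @param scene a [`vm_scene`][scene_config].
#' @param cfg a [detection_config()].
#' @param seed integer seed; the two cohorts use `seed + 1` and `seed + 2`.
#' @param out_dir output directory, created if needed; `NULL` skips
#'   writing.
#' @param ... forwarded to [analyze_cohort()] (e.g. `keep_profiles`).
#' @return List with both cohort results (`intact`, `amputated`), the
#'   combined `intervals`, the `report` and the `engagement` rate.
#' @export
run_pipeline <- function(n_intact = 30, n_amputated = 14,
                         trials_per_subject = 40, scene = desk_scene(),
                         cfg = detection_config(), seed = 1,
                         out_dir = NULL, ...) {
  res <- list()
  if (n_intact > 0) {
    res$intact <- analyze_cohort(n_intact, trials_per_subject,
                                 intact_profile(), scene, cfg,
                                 seed = seed + 1, ...)
  }
  if (n_amputated > 0) {
    res$amputated <- analyze_cohort(n_amputated, trials_per_subject,
                                    amputated_profile(), scene, cfg,
                                    seed = seed + 2, ...)
  }
  parts <- Filter(Negate(is.null), res[c("intact", "amputated")])
  res$intervals <- do.call(rbind, lapply(parts, `[[`, "intervals"))
  rownames(res$intervals) <- NULL
  res$engagement <- engagement_rate(
    unlist(lapply(parts, `[[`, "min_gaze_target")), cfg$fixation_px)
  res$report <- if (length(parts) == 2) interval_report(res$intervals)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    hdr <- c("# format: vm-report/1",
             sprintf("# seed: %s", seed),
             sprintf(paste0("# thresholds: fixation<%gpx velocity<%gdeg/s ",
                            "head>%gdeg/s arm>%gg muscles>%gx grasp<%gpx"),
                     cfg$fixation_px, cfg$saccade_deg_s, cfg$head_deg_s,
                     cfg$arm_g, cfg$muscle_multiplier, cfg$grasp_px))
    write_tsv_header <- function(df, file) {
      con <- file.path(out_dir, file)
      writeLines(hdr, con)
      suppressWarnings(utils::write.table(
        df, con, sep = "\t", row.names = FALSE, quote = FALSE,
        na = "NA", append = TRUE))
    }
    events <- do.call(rbind, lapply(parts, `[[`, "events"))
    write_tsv_header(events, "events.tsv")
    write_tsv_header(res$intervals, "intervals.tsv")
    if (!is.null(res$report)) write_tsv_header(res$report, "report.tsv")
    writeLines(c(hdr, sprintf("engagement\t%.6f", res$engagement)),
               file.path(out_dir, "engagement.tsv"))
  }
  res
}
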