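vm_interval_defs <- list(
  "fixation -> grasp" = c("fixation", "grasp"),
  "saccade -> fixation" = c("saccade", "fixation"),
  "saccade -> head" = c("saccade", "head"),
  "head -> arm" = c("head", "arm"),
  "arm -> muscles" = c("arm", "muscles")
)

#' Event-pair intervals
#'
#' Computes the five intervals of interest between detected events —
#' fixation->grasp, saccade->fixation, saccade->head, head->arm and
#' arm->muscles — as later event time minus earlier event time (negative
#' values are allowed, e.g. when a muscle activation precedes the
#' detectable arm movement). An interval is missing whenever either
#' endpoint was not detected.
#'
#' @param events a long data frame of per-trial events with columns
#'   `subject`, `group`, `trial`, `event`, `time`, `status` (as produced by
#'   [analyze_cohort()], or by stacking [detect_events()] results).
#' @return Long data frame `subject`, `group`, `trial`, `interval`,
#'   `value` (s, `NA` when missing).
#' @export
compute_intervals <- function(events) {
  key <- paste(events$subject, events$trial, sep = "\r")
  trials <- unique(data.frame(subject = events$subject,
                              group = events$group, trial = events$trial,
                              key = key, stringsAsFactors = FALSE))
  get_time <- function(ev) {
    ok <- events$event == ev & events$status == "detected"
    tt <- rep(NA_real_, nrow(trials))
    idx <- match(key[ok], trials$key)
    tt[idx] <- events$time[ok]
    tt
  }
  times <- lapply(unique(unlist(vm_interval_defs)), get_time)
  names(times) <- unique(unlist(vm_interval_defs))
  out <- do.call(rbind, lapply(names(vm_interval_defs), function(nm) {
    ab <- vm_interval_defs[[nm]]
    data.frame(subject = trials$subject, group = trials$group,
               trial = trials$trial, interval = nm,
               value = times[[ab[2]]] - times[[ab[1]]],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Quartile summary
#'
#' Count and quartiles (Q1, median, Q3) of the non-missing values, using
#' linear interpolation between order statistics
#' ([stats::quantile()] type 7).
#'
#' @param values numeric vector (may contain `NA`).
#' @return Named vector `n`, `q1`, `median`, `q3`.
#' @export
quartile_summary <- function(values) {
  v <- values[!is.na(values)]
  if (!length(v)) return(c(n = 0, q1 = NA_real_, median = NA_real_,
                           q3 = NA_real_))
  q <- unname(stats::quantile(v, c(0.25, 0.5, 0.75), type = 7))
  c(n = length(v), q1 = q[1], median = q[2], q3 = q[3])
}

#' Two-sample KS comparison of per-subject mean intervals
#'
#' Compares the distributions of per-subject average intervals between two
#' groups with a two-sample Kolmogorov-Smirnov test: the statistic is the
#' supremum difference of the two empirical distribution functions and the
#' p-value uses the asymptotic two-sided formula at the effective sample
#' size `n*m/(n+m)` (an exact small-sample computation is available via
#' `exact = TRUE`). Subjects without any valid interval are excluded.
#'
#' @param means_a,means_b per-subject mean intervals for the two groups.
#' @param exact compute the exact p-value instead of the asymptotic one.
#' @return List `statistic`, `p_value`, `n_a`, `n_b`.
#' @export
ks_group_test <- function(means_a, means_b, exact = FALSE) {
  a <- means_a[!is.na(means_a)]
  b <- means_b[!is.na(means_b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("need at least two subjects with valid means per group",
         call. = FALSE)
  }
  kt <- suppressWarnings(stats::ks.test(a, b, exact = exact))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       n_a = length(a), n_b = length(b))
}

#' Per-subject mean intervals
#'
#' @param intervals output of [compute_intervals()].
#' @param interval interval name.
#' @return Data frame `subject`, `group`, `mean` (subjects with no valid
#'   value of this interval are dropped).
#' @export
subject_means <- function(intervals, interval) {
  d <- intervals[intervals$interval == interval & !is.na(intervals$value), ]
  if (!nrow(d)) return(data.frame(subject = character(), group = character(),
                                  mean = numeric()))
  agg <- stats::aggregate(value ~ subject + group, data = d, FUN = mean)
  data.frame(subject = agg$subject, group = agg$group, mean = agg$value,
             stringsAsFactors = FALSE)
}

#' Engagement rate
#'
#' Fraction of trials whose minimum gaze-target distance over the whole
#' trial (at the native frame rate) falls below the fixation distance
#' threshold at least once. Trials without any gaze-target distance count
#' as not engaged.
#'
#' @param min_gaze_target per-trial minimum gaze-target distances (px).
#' @param threshold_px fixation distance threshold.
#' @return Fraction in `[0, 1]`.
#' @export
engagement_rate <- function(min_gaze_target, threshold_px = 20) {
  if (!length(min_gaze_target)) stop("no trials", call. = FALSE)
  mean(!is.na(min_gaze_target) & min_gaze_target < threshold_px)
}

#' Time-locked modality profile over trials
#'
#' Per-bin median and interquartile envelope of a gridded modality over
#' all trials of a group: the solid-line/shaded-area summaries of the
#' coordination profiles. Bins in which more than `max_missing` of trials
#' are missing are omitted (all-`NA` summary, `omitted = TRUE`).
#'
#' @param mat numeric matrix, trials in rows, grid bins in columns.
#' @param time bin centres (s).
#' @param max_missing maximum tolerated missing fraction per bin.
#' @return Data frame `time`, `median`, `q1`, `q3`, `n`, `frac_missing`,
#'   `omitted`.
#' @export
profile_aggregate <- function(mat, time, max_missing = 0.9) {
  stopifnot(is.matrix(mat), ncol(mat) == length(time))
  frac_missing <- colMeans(is.na(mat))
  n <- colSums(!is.na(mat))
  qs <- apply(mat, 2, function(col) {
    v <- col[!is.na(col)]
    if (!length(v)) return(c(NA_real_, NA_real_, NA_real_))
    stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  })
  out <- data.frame(time = time, median = qs[2, ], q1 = qs[1, ],
                    q3 = qs[3, ], n = n, frac_missing = frac_missing,
                    omitted = frac_missing > max_missing)
  out[out$omitted, c("median", "q1", "q3")] <- NA_real_
  out
}

#' Interval statistics report
#'
#' Builds the per-interval statistical summary comparing the two groups:
#' count and quartiles of the pooled trial intervals per group, plus the
#' KS comparison of per-subject means.
#'
#' @param intervals combined [compute_intervals()] output for both groups.
#' @param group_a,group_b group labels to compare.
#' @param exact forwarded to [ks_group_test()].
#' @return Data frame with one row per interval: `interval`, `n_a`, `q1_a`,
#'   `median_a`, `q3_a`, `n_b`, `q1_b`, `median_b`, `q3_b`, `ks`, `p`.
#' @export
interval_report <- function(intervals, group_a = "intact",
                            group_b = "amputated", exact = FALSE) {
  rows <- lapply(names(vm_interval_defs), function(nm) {
    va <- intervals$value[intervals$interval == nm &
                            intervals$group == group_a]
    vb <- intervals$value[intervals$interval == nm &
                            intervals$group == group_b]
    sa <- quartile_summary(va)
    sb <- quartile_summary(vb)
    sm <- subject_means(intervals, nm)
    ks <- tryCatch(
      ks_group_test(sm$mean[sm$group == group_a],
                    sm$mean[sm$group == group_b], exact = exact),
      error = function(e) list(statistic = NA_real_, p_value = NA_real_)
    )
    data.frame(interval = nm,
               n_a = sa[["n"]], q1_a = sa[["q1"]], median_a = sa[["median"]],
               q3_a = sa[["q3"]],
               n_b = sb[["n"]], q1_b = sb[["q1"]], median_b = sb[["median"]],
               q3_b = sb[["q3"]],
               ks = ks$statistic, p = ks$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
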