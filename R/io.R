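#' On-disk trial layout
#'
#' Writes and reads the documented, versioned dataset layout: one directory
#' per trial containing tab-separated stream tables (`gaze.tsv`,
#' `gyro.tsv`, `acc.tsv`, `emg.tsv`; seconds, mm, px, deg/s, g, arbitrary
#' mV), a `meta.tsv` key-value table (including the planted schedule), and
#' `masks.tsv`, an index of all segmentation instances (frame, time, class,
#' score, area) with the binary mask stored losslessly as a run-length
#' encoded string over the column-major flattened matrix. A cohort
#' directory holds one trial directory per row of its `manifest.tsv`
#' (subject, group, trial, seed). All files start with a
#' `# format: vm-.../1` version header.
#'
#' `read_cohort()` skips unreadable trial directories with a warning
#' rather than failing the whole cohort.
#'
#' @param trial a [`vm_trial`][generate_trial].
#' @param dir target/source directory.
#' @param cohort a [`vm_cohort`][generate_cohort].
#' @return `read_trial()` returns a `vm_trial` (the `scene` is restored
#'   from the metadata needed by the analysis: frame size, rates, window);
#'   `read_cohort()` a list of trials with a `manifest` attribute.
#' @name dataset-io
NULL

fmt_header <- function(kind) sprintf("# format: vm-%s/1", kind)

write_stream <- function(df, path, kind) {
  writeLines(fmt_header(kind), path)
  suppressWarnings(utils::write.table(df, path, sep = "\t",
                                      row.names = FALSE, quote = FALSE,
                                      na = "NA", append = TRUE))
}

read_stream <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    na.strings = "NA", stringsAsFactors = FALSE)
}

rle_encode <- function(mask) {
  r <- rle(as.logical(as.vector(mask)))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  paste(sprintf("%d:%d", starts[keep], r$lengths[keep]), collapse = ",")
}

rle_decode <- function(code, h, w) {
  out <- matrix(FALSE, h, w)
  if (nzchar(code)) {
    parts <- strsplit(strsplit(code, ",", fixed = TRUE)[[1]], ":",
                      fixed = TRUE)
    for (p in parts) {
      s <- as.integer(p[1]); l <- as.integer(p[2])
      out[s:(s + l - 1L)] <- TRUE
    }
  }
  out
}

#' @rdname dataset-io
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_stream(trial$gaze, file.path(dir, "gaze.tsv"), "gaze")
  write_stream(trial$gyro, file.path(dir, "gyro.tsv"), "gyro")
  write_stream(trial$acc, file.path(dir, "acc.tsv"), "acc")
  write_stream(trial$emg, file.path(dir, "emg.tsv"), "emg")

  seg <- trial$frames
  rows <- list()
  for (j in seq_along(seg$frames)) {
    for (inst in seg$frames[[j]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        frame = seg$frame_index[j], time = seg$times[j],
        class = inst$class, score = inst$score, area = inst$area,
        rle = rle_encode(inst$mask), stringsAsFactors = FALSE)
    }
  }
  write_stream(do.call(rbind, rows), file.path(dir, "masks.tsv"), "masks")

  sc <- trial$scene
  sched <- trial$schedule
  kv <- c(
    subject = trial$meta$subject, group = trial$meta$group,
    trial_id = trial$meta$trial_id, target_class = trial$meta$target_class,
    task_type = trial$meta$task_type,
    instruction = trial$meta$instruction %||% NA,
    position = trial$meta$position, stimulus_end = trial$meta$stimulus_end,
    width = sc$width, height = sc$height, fps = sc$fps,
    gaze_hz = sc$gaze_hz, gyro_hz = sc$gyro_hz, acc_hz = sc$acc_hz,
    emg_hz = sc$emg_hz, focal_px = sc$focal_px,
    window_start = sc$window[1], window_end = sc$window[2],
    target_x = sc$target_center[1], target_y = sc$target_center[2],
    target_r = sc$target_radius,
    sched_saccade = sched$times[["saccade"]],
    sched_fixation = sched$times[["fixation"]],
    sched_head = sched$times[["head"]],
    sched_arm = sched$times[["arm"]],
    sched_muscles = sched$times[["muscles"]],
    sched_grasp = sched$times[["grasp"]],
    touch = sched$touch, low_accuracy = sched$low_accuracy,
    stop_short_px = sched$stop_short_px
  )
  meta <- data.frame(key = names(kv), value = as.character(kv),
                     stringsAsFactors = FALSE)
  write_stream(meta, file.path(dir, "meta.tsv"), "meta")
  invisible(dir)
}

#' @rdname dataset-io
#' @export
read_trial <- function(dir) {
  meta_df <- read_stream(file.path(dir, "meta.tsv"))
  kv <- stats::setNames(meta_df$value, meta_df$key)
  num <- function(k) as.numeric(kv[[k]])
  scene <- scene_config(
    width = num("width"), height = num("height"), fps = num("fps"),
    gaze_hz = num("gaze_hz"), gyro_hz = num("gyro_hz"),
    acc_hz = num("acc_hz"), emg_hz = num("emg_hz"),
    focal_px = num("focal_px"),
    target_center = c(num("target_x"), num("target_y")),
    target_radius = num("target_r"),
    window = c(num("window_start"), num("window_end"))
  )
  masks <- read_stream(file.path(dir, "masks.tsv"))
  frame_index <- sort(unique(masks$frame))
  times <- vapply(frame_index,
                  function(k) masks$time[masks$frame == k][1], numeric(1))
  frames <- lapply(frame_index, function(k) {
    sel <- which(masks$frame == k)
    lapply(sel, function(i) {
      new_instance(masks$class[i], masks$score[i],
                   rle_decode(masks$rle[i], scene$height, scene$width), k)
    })
  })
  seg <- structure(list(times = times, frame_index = frame_index,
                        frames = frames, width = scene$width,
                        height = scene$height),
                   class = "vm_segmentation")
  sched_times <- c(saccade = num("sched_saccade"),
                   fixation = num("sched_fixation"),
                   head = num("sched_head"), arm = num("sched_arm"),
                   muscles = num("sched_muscles"),
                   grasp = num("sched_grasp"))
  schedule <- structure(
    list(times = sched_times, touch = as.logical(kv[["touch"]]),
         low_accuracy = as.logical(kv[["low_accuracy"]]),
         window = scene$window, stop_short_px = num("stop_short_px")),
    class = "vm_schedule")
  gaze <- read_stream(file.path(dir, "gaze.tsv"))
  class(gaze) <- c("vm_gaze", "data.frame")
  trial <- list(
    meta = list(subject = kv[["subject"]], group = kv[["group"]],
                trial_id = as.integer(kv[["trial_id"]]),
                target_class = kv[["target_class"]],
                task_type = kv[["task_type"]],
                instruction = kv[["instruction"]],
                position = kv[["position"]],
                stimulus_end = num("stimulus_end")),
    schedule = schedule, gaze = gaze, frames = seg,
    gyro = read_stream(file.path(dir, "gyro.tsv")),
    acc = read_stream(file.path(dir, "acc.tsv")),
    emg = read_stream(file.path(dir, "emg.tsv")),
    scene = scene
  )
  class(trial) <- "vm_trial"
  trial
}

#' @rdname dataset-io
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- cohort$plan$table
  rows <- list()
  for (i in seq_along(cohort$trials)) {
    tr <- cohort$trials[[i]]
    tdir <- sprintf("%s_t%03d", tr$meta$subject, tr$meta$trial_id)
    write_trial(tr, file.path(dir, tdir))
    rows[[i]] <- data.frame(subject = tr$meta$subject,
                            group = tr$meta$group,
                            trial = tr$meta$trial_id,
                            seed = tab$seed[i], dir = tdir,
                            stringsAsFactors = FALSE)
  }
  write_stream(do.call(rbind, rows), file.path(dir, "manifest.tsv"),
               "manifest")
  invisible(dir)
}

#' @rdname dataset-io
#' @export
read_cohort <- function(dir) {
  manifest <- read_stream(file.path(dir, "manifest.tsv"))
  trials <- list()
  skipped <- 0L
  for (i in seq_len(nrow(manifest))) {
    tr <- tryCatch(suppressWarnings(read_trial(file.path(dir, manifest$dir[i]))),
                   error = function(e) NULL)
    if (is.null(tr)) {
      warning("skipping unreadable trial directory: ", manifest$dir[i],
              call. = FALSE)
      skipped <- skipped + 1L
    } else {
      trials[[length(trials) + 1L]] <- tr
    }
  }
  attr(trials, "manifest") <- manifest
  attr(trials, "skipped") <- skipped
  trials
}
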