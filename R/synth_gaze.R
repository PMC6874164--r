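#' Synthesize a gaze series for a planted schedule
#'
#' Generates a 100 Hz (configurable) gaze stream consistent with a pinhole
#' camera model: 2-D gaze in frame pixels, the 3-D gaze point in
#' scene-camera coordinates (mm) and left/right pupil positions, such that
#' recentering the 3-D gaze point on the mean pupil position and projecting
#' it reproduces the frame-pixel gaze exactly.
#'
#' The trajectory rests at the scene's start point, then travels to a dwell
#' point on the target along a smooth quarter-sine velocity bump starting at
#' the planted saccade onset. The bump is timed so that the pixel distance
#' to the target-mask contour crosses just below 20 px exactly at the
#' planted fixation time, with angular velocity above 70 deg/s throughout
#' the approach. When the planted transit is too slow to sustain a saccadic
#' velocity, the movement is split into a fast hypometric saccade followed
#' by a small corrective saccade that lands at the planted fixation time; in
#' that case the velocity dips below threshold between the two movements,
#' which (as in real recordings) leaves the saccade event undetectable while
#' preserving the fixation.
#'
#' Per-trial systematic accuracy offsets, smoothed per-sample angular noise,
#' and contiguous pupil dropouts (shorter and longer than the 0.075 s
#' interpolation limit) are added according to the profile. For
#' low-accuracy trials the dwell point is displaced toward the start point
#' so the gaze-target distance never falls below the 20 px fixation
#' threshold.
#'
#' @param schedule a [`vm_schedule`][sample_schedule].
#' @param scene a [`vm_scene`][scene_config].
#' @param profile the [`vm_profile`][timing_profile] the schedule was drawn
#'   from.
#' @param seed optional integer seed.
#' @return A `data.frame` of class `vm_gaze` with columns `t`, 3-D gaze
#'   `gx, gy, gz` (mm), pupils `plx, ply, plz, prx, pry, prz` (mm, `NA`
#'   during dropouts), frame-pixel gaze `fx, fy`, and `pupils_valid`.
#' @export
synth_gaze <- function(schedule, scene, profile, seed = NULL) {
  stopifnot(inherits(schedule, "vm_schedule"), inherits(scene, "vm_scene"),
            inherits(profile, "vm_profile"))
  start <- scene$gaze_start
  center <- scene$target_center
  r <- scene$target_radius
  if (vec_norm(start - center) - r < 100) {
    stop("gaze start point must be at least 100 px (mask distance) from ",
         "the target", call. = FALSE)
  }
  f <- scene$focal_px
  pxdeg <- px_per_degree(scene)
  hz <- scene$gaze_hz
  win <- scene$window

  with_seed(seed, {
    i <- seq(floor((win[1] - 0.08) * hz), ceiling((win[2] + 0.08) * hz))
    t <- i / hz
    n <- length(t)

    # dwell point: systematic accuracy offset, or a deliberate offset beyond
    # the fixation threshold for low-accuracy trials (placed on the near side
    # of the target so the approach path never dips under the threshold)
    fix_thr <- 20
    if (schedule$low_accuracy) {
      m <- stats::runif(1, profile$low_accuracy_margin_px[1],
                        profile$low_accuracy_margin_px[2])
      off <- unit_vec(start - center) * (r + fix_thr + m)
    } else {
      off <- stats::rnorm(2, 0, profile$gaze_accuracy_deg * pxdeg)
    }
    dwell <- center + off

    pos <- gaze_path(t, schedule, start, dwell, center, r, pxdeg)

    noise_px <- profile$gaze_noise_deg * pxdeg
    x <- pos[, 1] + smooth_noise(n, noise_px)
    y <- pos[, 2] + smooth_noise(n, noise_px)

    # pinhole back-projection at the configured manipulation depth
    cx <- (scene$width - 1) / 2
    cy <- (scene$height - 1) / 2
    depth <- scene$gaze_depth_mm
    ghat <- cbind((x - cx) / f * depth, (y - cy) / f * depth, depth)
    pl <- c(-32, 28, -38) + stats::rnorm(3, 0, 1)
    pr <- c(32, 28, -38) + stats::rnorm(3, 0, 1)
    pbar <- (pl + pr) / 2
    g <- sweep(ghat, 2, pbar, "+")

    out <- data.frame(
      t = t, gx = g[, 1], gy = g[, 2], gz = g[, 3],
      plx = pl[1], ply = pl[2], plz = pl[3],
      prx = pr[1], pry = pr[2], prz = pr[3],
      fx = x, fy = y, pupils_valid = TRUE
    )

    # contiguous pupil dropouts, both below and above the 0.075 s limit
    if (profile$dropout_rate > 0) {
      n_gaps <- stats::rpois(1, profile$dropout_rate * (t[n] - t[1]))
      if (n_gaps > 0) {
        for (k in seq_len(n_gaps)) {
          len <- if (stats::runif(1) < profile$dropout_short_frac) {
            sample(1:6, 1)
          } else {
            sample(8:16, 1)
          }
          s0 <- sample(seq_len(max(1L, n - len - 1L)), 1) + 1L
          idx <- s0:min(n, s0 + len - 1L)
          out[idx, c("plx", "ply", "plz", "prx", "pry", "prz")] <- NA_real_
          out$pupils_valid[idx] <- FALSE
        }
      }
    }
    class(out) <- c("vm_gaze", "data.frame")
    out
  })
}

# Deterministic gaze path in frame pixels (n x 2 matrix).
gaze_path <- function(t, schedule, start, dwell, center, r, pxdeg) {
  t_s <- schedule$times[["saccade"]]
  t_f <- schedule$times[["fixation"]]
  D <- vec_norm(dwell - start)
  u <- unit_vec(dwell - start)

  # arc length along start->dwell where the mask distance crosses just
  # below the fixation threshold (line/circle intersection); low-accuracy
  # dwell points never cross, so anchor near the dwell instead
  s_star <- line_circle_arc(start, u, center, r + 19)
  if (is.na(s_star) || s_star > D) s_star <- max(D - 15, 0.5 * D)

  Ttr <- t_f - t_s
  ratio <- min(s_star / D, 1)
  Ta <- Ttr * (pi / 2) / asin(ratio)
  vpeak <- D * pi / (2 * Ta)
  vcross <- vpeak * sqrt(1 - ratio^2)
  v70 <- 70 * pxdeg # px/s equivalent of the 70 deg/s saccade threshold

  s_of_t <- numeric(length(t))
  if (vcross >= 1.15 * v70) {
    # single smooth quarter-sine flight; velocity stays saccadic up to and
    # beyond the fixation crossing, peaking at movement onset
    ph <- pmin(pmax((t - t_s) / Ta, 0), 1)
    s_of_t <- D * sin(ph * pi / 2)
  } else {
    # hypometric main saccade + corrective saccade landing at t_f
    s1 <- line_circle_arc(start, u, center, r + 40)
    if (is.na(s1) || s1 >= s_star) s1 <- 0.7 * s_star
    vp1 <- max(2.5 * v70, s1 * pi / (2 * 0.12))
    T1 <- s1 * pi / (2 * vp1)
    D2 <- D - s1
    s2s <- s_star - s1
    T2a <- D2 * pi / (2 * (2 * v70))
    tau2 <- (2 * T2a / pi) * asin(min(s2s / D2, 1))
    t2 <- max(t_f - tau2, t_s + T1 + 0.04)
    ph1 <- pmin(pmax((t - t_s) / T1, 0), 1)
    ph2 <- pmin(pmax((t - t2) / T2a, 0), 1)
    s_of_t <- s1 * sin(ph1 * pi / 2) + D2 * sin(ph2 * pi / 2)
  }
  cbind(start[1] + u[1] * s_of_t, start[2] + u[2] * s_of_t)
}

# Smallest positive arc length s with |p0 + s*u - c| = R, or NA.
line_circle_arc <- function(p0, u, cc, R) {
  d <- p0 - cc
  b <- sum(u * d)
  disc <- b^2 - (sum(d * d) - R^2)
  if (disc < 0) return(NA_real_)
  roots <- c(-b - sqrt(disc), -b + sqrt(disc))
  roots <- roots[roots > 0]
  if (!length(roots)) return(NA_real_)
  min(roots)
}
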