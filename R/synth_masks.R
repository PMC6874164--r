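#' Synthesize per-frame instance segmentations
#'
#' Renders the target object (a filled disc) in every video frame and, from
#' the planted arm onset onward, a "person" instance: a wedge entering from
#' the bottom edge of the frame whose tip approaches the target. For
#' touching trials the wedge reaches mask contact (limb-target distance
#' below 5 px) exactly at the planted grasp time and then overlaps the
#' target; for non-touching trials it stops short at the subject-specific
#' pixel offset and hovers there.
#'
#' @inheritParams synth_gaze
#' @param target_class class label given to the target instance.
#' @param distractors if `TRUE`, adds three static distractor instances per
#'   frame to exercise the selection rules: a smaller same-class instance
#'   (score 0.9), a same-class instance with score 0.6 (below the 0.8
#'   acceptance threshold) and a small "person" instance in the upper half
#'   of the frame.
#' @return A `vm_segmentation`: list with `times` (frame timestamps,
#'   seconds) and `frames`, one list of instances per frame. Each instance
#'   is a `vm_instance` with fields `class`, `score`, `mask` (logical
#'   `height x width` matrix), `frame` and `area`.
#' @export
synth_masks <- function(schedule, scene, profile, seed = NULL,
                        target_class = "can", distractors = FALSE) {
  stopifnot(inherits(schedule, "vm_schedule"), inherits(scene, "vm_scene"),
            inherits(profile, "vm_profile"))
  W <- scene$width; H <- scene$height
  win <- scene$window
  center <- scene$target_center
  r <- scene$target_radius

  with_seed(seed, {
    k <- seq(ceiling((win[1] - 0.06) * scene$fps),
             floor((win[2] + 0.06) * scene$fps))
    times <- k / scene$fps

    target_mask <- raster_disc(center, r, W, H)
    target_inst <- function(frame) {
      new_instance(target_class, 0.95, target_mask, frame)
    }

    extras <- list()
    if (distractors) {
      m_small <- raster_disc(c(0.30 * W, 0.25 * H), 0.6 * r, W, H)
      m_low <- raster_disc(c(0.50 * W, 0.20 * H), 0.8 * r, W, H)
      m_up <- raster_disc(c(0.10 * W, 0.15 * H), max(4, 0.4 * r), W, H)
      extras <- list(
        function(frame) new_instance(target_class, 0.90, m_small, frame),
        function(frame) new_instance(target_class, 0.60, m_low, frame),
        function(frame) new_instance("person", 0.90, m_up, frame)
      )
    }

    # limb geometry: enters at the bottom edge, tip travels toward the
    # contact point on the target contour
    entry <- c(scene$limb_base_x, H - 1)
    contact <- center + r * unit_vec(entry - center)
    dir_out <- unit_vec(entry - contact)
    d_path <- vec_norm(entry - contact)

    t_arm <- schedule$times[["arm"]]
    t_g <- schedule$times[["grasp"]]
    touch <- schedule$touch && !is.na(t_g)
    approach_start <- t_arm
    if (touch && t_g - t_arm < 0.15) approach_start <- t_g - 0.2
    stop_px <- schedule$stop_short_px
    if (is.na(stop_px)) stop_px <- max(12, sample_dist(profile$stop_short_px))

    tip_dist <- function(tt) {
      if (touch) {
        Tr <- max(t_g - approach_start, 1e-3)
        if (tt <= t_g) {
          3.5 + (d_path - 3.5) * max(0, (t_g - tt) / Tr)
        } else {
          max(3.5 - 7 * (tt - t_g) / 0.15, -3.5)
        }
      } else {
        # raster margin keeps the mask distance >= the configured offset;
        # the hold point is kept inside the frame so the wedge tip remains
        # the closest limb point to the target
        hold <- min(stop_px + 1.5, d_path - 18)
        hold + (d_path - hold) * max(0, 1 - (tt - approach_start) / 0.8)
      }
    }

    frames <- vector("list", length(times))
    for (j in seq_along(times)) {
      tt <- times[j]
      inst <- list(target_inst(k[j]))
      for (ex in extras) inst <- c(inst, list(ex(k[j])))
      if (tt >= approach_start) {
        tip <- contact + dir_out * tip_dist(tt)
        limb <- raster_wedge(tip, entry, scene$limb_tip_halfwidth,
                             scene$limb_base_halfwidth, W, H)
        if (any(limb)) {
          inst <- c(inst, list(new_instance("person", 0.90, limb, k[j])))
        }
      }
      frames[[j]] <- inst
    }
    structure(list(times = times, frame_index = k, frames = frames,
                   width = W, height = H),
              class = "vm_segmentation")
  })
}

new_instance <- function(class, score, mask, frame) {
  structure(list(class = class, score = score, mask = mask,
                 frame = frame, area = sum(mask)),
            class = "vm_instance")
}

# Filled disc; pixel centers at integer 0-based (col=x, row=y) coordinates.
raster_disc <- function(center, r, W, H) {
  dy2 <- (0:(H - 1) - center[2])^2
  dx2 <- (0:(W - 1) - center[1])^2
  outer(dy2, dx2, "+") <= r^2
}

# Filled symmetric wedge (trapezoid) from a base segment centred below the
# frame's bottom edge to a tip segment at `tip`, rasterized over its
# bounding box only.
raster_wedge <- function(tip, entry, tip_hw, base_hw, W, H) {
  axis <- entry - tip
  if (vec_norm(axis) < 1e-9) axis <- c(0, 1)
  perp <- unit_vec(c(-axis[2], axis[1]))
  base_c <- entry + unit_vec(axis) * 4 # base sits just below the frame edge
  v <- list(tip + perp * tip_hw, tip - perp * tip_hw,
            base_c - perp * base_hw, base_c + perp * base_hw)
  xs <- vapply(v, `[`, numeric(1), 1)
  ys <- vapply(v, `[`, numeric(1), 2)
  shoelace <- sum(xs * ys[c(2:4, 1)] - xs[c(2:4, 1)] * ys)
  if (shoelace < 0) { # enforce counter-clockwise winding
    v <- rev(v); xs <- rev(xs); ys <- rev(ys)
  }
  x0 <- max(0L, floor(min(xs))); x1 <- min(W - 1L, ceiling(max(xs)))
  y0 <- max(0L, floor(min(ys))); y1 <- min(H - 1L, ceiling(max(ys)))
  out <- matrix(FALSE, H, W)
  if (x0 > x1 || y0 > y1) return(out)
  gx <- matrix(x0:x1, y1 - y0 + 1, x1 - x0 + 1, byrow = TRUE)
  gy <- matrix(y0:y1, y1 - y0 + 1, x1 - x0 + 1)
  inside <- !logical(length(gx))
  dim(inside) <- dim(gx)
  for (e in 1:4) {
    a <- v[[e]]; b <- v[[if (e == 4) 1 else e + 1]]
    # convex polygon in counter-clockwise order: keep the left side
    cr <- (b[1] - a[1]) * (gy - a[2]) - (b[2] - a[2]) * (gx - a[1])
    inside <- inside & (cr >= 0)
  }
  if (!any(inside)) return(out)
  out[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1)] <- inside
  out
}
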