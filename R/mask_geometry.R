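#' Instance selection rules
#'
#' `select_target()` keeps instances of the trial's target class with a
#' certainty score of at least `min_score` and returns the largest by area
#' (ties broken by the lowest instance index). `select_limb()` keeps
#' "person" instances with sufficient score whose mask centroid row lies
#' strictly in the lower half of the frame (centroid row, 0-based,
#' `> height / 2`) and again returns the largest. Both return `NULL` when
#' no instance qualifies — absence is a value, not an error.
#'
#' @param instances list of [`vm_instance`][synth_masks] objects for one
#'   frame.
#' @param target_class class label of the grasp target.
#' @param frame_height frame height in px.
#' @param min_score minimum certainty score.
#' @return The selected `vm_instance`, or `NULL`.
#' @export
select_target <- function(instances, target_class, min_score = 0.8) {
  best <- NULL
  for (inst in instances) {
    if (inst$class != target_class || inst$score < min_score) next
    if (is.null(best) || inst$area > best$area) best <- inst
  }
  best
}

#' @rdname select_target
#' @export
select_limb <- function(instances, frame_height, min_score = 0.8) {
  best <- NULL
  for (inst in instances) {
    if (inst$class != "person" || inst$score < min_score) next
    rows <- which(rowSums(inst$mask) > 0) - 1L
    centroid_row <- sum(rows * rowSums(inst$mask)[rows + 1L]) / inst$area
    if (centroid_row <= frame_height / 2) next # strictly lower half
    if (is.null(best) || inst$area > best$area) best <- inst
  }
  best
}

#' Contour of a binary mask
#'
#' Returns the boundary pixels of a mask: all set pixels that are
#' 8-connected-adjacent to at least one unset pixel or to the frame border.
#'
#' @param mask logical matrix (`height x width`), nonempty.
#' @return Integer matrix with columns `row`, `col` (0-based pixel
#'   coordinates).
#' @export
mask_contour <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) stop("mask is empty", call. = FALSE)
  h <- nrow(mask)
  rows <- (idx - 1L) %% h + 1L
  cols <- (idx - 1L) %/% h + 1L
  r0 <- min(rows); r1 <- max(rows); c0 <- min(cols); c1 <- max(cols)
  # work on the tight bounding box, padded with FALSE: pixels outside the
  # box are unset and the frame border also counts as boundary, so the
  # padded computation is exact
  hh <- r1 - r0 + 3L; ww <- c1 - c0 + 3L
  pad <- matrix(FALSE, hh, ww)
  pad[2:(hh - 1L), 2:(ww - 1L)] <- mask[r0:r1, c0:c1, drop = FALSE]
  core <- pad[2:(hh - 1L), 2:(ww - 1L), drop = FALSE]
  # a set pixel is interior iff all 8 neighbours are set
  interior <- core &
    pad[1:(hh - 2L), 2:(ww - 1L), drop = FALSE] &
    pad[3:hh, 2:(ww - 1L), drop = FALSE] &
    pad[2:(hh - 1L), 1:(ww - 2L), drop = FALSE] &
    pad[2:(hh - 1L), 3:ww, drop = FALSE] &
    pad[1:(hh - 2L), 1:(ww - 2L), drop = FALSE] &
    pad[1:(hh - 2L), 3:ww, drop = FALSE] &
    pad[3:hh, 1:(ww - 2L), drop = FALSE] &
    pad[3:hh, 3:ww, drop = FALSE]
  bidx <- which(core & !interior, arr.ind = TRUE)
  cbind(row = bidx[, 1] + r0 - 2L, col = bidx[, 2] + c0 - 2L)
}

#' Minimum pixel distance between a point and a mask contour
#'
#' Euclidean distance (px) from a point in frame coordinates to the contour
#' of a binary mask; 0 when the point's containing pixel belongs to the
#' mask (overlap). Points outside the frame bounds are still measured
#' against the contour and flagged via the `outside_frame` attribute.
#'
#' @param point `c(x, y)` pixel coordinates (0-based, pixel centres at
#'   integers).
#' @param mask logical matrix, nonempty.
#' @param contour optionally the precomputed [mask_contour()] of `mask`.
#' @return Distance in px (`>= 0`).
#' @examples
#' m <- matrix(FALSE, 8, 8); m[5, 4] <- TRUE # pixel (row 4, col 3)
#' point_mask_distance(c(0, 0), m)           # 3-4-5 triangle: 5
#' @export
point_mask_distance <- function(point, mask, contour = NULL) {
  stopifnot(length(point) == 2L, all(is.finite(point)))
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  h <- nrow(mask); w <- ncol(mask)
  px <- round(point[1]); py <- round(point[2])
  inside_frame <- px >= 0 && px <= w - 1 && py >= 0 && py <= h - 1
  if (inside_frame && mask[py + 1, px + 1]) {
    out <- 0
  } else {
    ct <- contour %||% mask_contour(mask)
    out <- sqrt(min((ct[, "col"] - point[1])^2 + (ct[, "row"] - point[2])^2))
  }
  attr(out, "outside_frame") <- !inside_frame
  out
}

#' Minimum pixel distance between two mask contours
#'
#' 0 when the masks share any pixel; otherwise the minimum pairwise
#' Euclidean distance between their contour pixels. Symmetric in its
#' arguments.
#'
#' @param mask_a,mask_b logical matrices of identical size, nonempty.
#' @param contour_a,contour_b optional precomputed contours.
#' @return Distance in px.
#' @export
mask_mask_distance <- function(mask_a, mask_b,
                               contour_a = NULL, contour_b = NULL) {
  if (!any(mask_a) || !any(mask_b)) stop("mask is empty", call. = FALSE)
  ca <- contour_a %||% mask_contour(mask_a)
  cb <- contour_b %||% mask_contour(mask_b)
  # overlap test restricted to the bounding-box intersection
  r0 <- max(min(ca[, "row"]), min(cb[, "row"])) + 1L
  r1 <- min(max(ca[, "row"]), max(cb[, "row"])) + 1L
  c0 <- max(min(ca[, "col"]), min(cb[, "col"])) + 1L
  c1 <- min(max(ca[, "col"]), max(cb[, "col"])) + 1L
  if (r0 <= r1 && c0 <= c1 &&
      any(mask_a[r0:r1, c0:c1] & mask_b[r0:r1, c0:c1])) {
    return(0)
  }
  dr <- outer(ca[, "row"], cb[, "row"], "-")
  dc <- outer(ca[, "col"], cb[, "col"], "-")
  sqrt(min(dr * dr + dc * dc))
}

#' Per-frame distance series for a trial
#'
#' For each video frame, applies the instance selection rules and computes
#' the three pixel distances of interest: gaze-target, gaze-limb and
#' limb-target. The gaze sample used for a frame is the one nearest in time
#' to the frame timestamp, within half a frame period; distances are
#' missing whenever an operand (instance or gaze sample) is absent.
#' Contours of instances whose mask is unchanged from the previous frame
#' (typically the static target) are reused rather than recomputed.
#'
#' @param trial a [`vm_trial`][generate_trial].
#' @param min_score certainty-score threshold for instance selection.
#' @return Data frame `frame`, `t`, `gaze_target`, `gaze_limb`,
#'   `limb_target` (px, `NA` when undefined).
#' @export
distance_series <- function(trial, min_score = 0.8) {
  seg <- trial$frames
  if (is.null(seg) || !length(seg$frames)) {
    stop("trial has no segmentation frames", call. = FALSE)
  }
  nt <- length(seg$times)
  gaze_t <- trial$gaze$t
  gx <- trial$gaze$fx
  gy <- trial$gaze$fy
  half_period <- 0.5 / trial$scene$fps
  target_class <- trial$meta$target_class
  H <- seg$height

  gt <- gl <- lt <- rep(NA_real_, nt)
  prev_t_mask <- NULL; prev_t_ct <- NULL
  prev_l_mask <- NULL; prev_l_ct <- NULL
  for (j in seq_len(nt)) {
    inst <- seg$frames[[j]]
    tgt <- select_target(inst, target_class, min_score)
    limb <- select_limb(inst, H, min_score)
    ct_t <- NULL
    if (!is.null(tgt)) {
      if (!is.null(prev_t_mask) && identical(tgt$mask, prev_t_mask)) {
        ct_t <- prev_t_ct
      } else {
        ct_t <- mask_contour(tgt$mask)
      }
      prev_t_mask <- tgt$mask; prev_t_ct <- ct_t
    }
    ct_l <- NULL
    if (!is.null(limb)) {
      if (!is.null(prev_l_mask) && identical(limb$mask, prev_l_mask)) {
        ct_l <- prev_l_ct
      } else {
        ct_l <- mask_contour(limb$mask)
      }
      prev_l_mask <- limb$mask; prev_l_ct <- ct_l
    }

    # nearest gaze sample within half a frame period
    gi <- which.min(abs(gaze_t - seg$times[j]))
    has_gaze <- length(gi) == 1 &&
      abs(gaze_t[gi] - seg$times[j]) <= half_period &&
      is.finite(gx[gi]) && is.finite(gy[gi])
    pt <- if (has_gaze) c(gx[gi], gy[gi]) else NULL

    if (!is.null(tgt) && !is.null(pt)) {
      gt[j] <- as.numeric(point_mask_distance(pt, tgt$mask, ct_t))
    }
    if (!is.null(limb) && !is.null(pt)) {
      gl[j] <- as.numeric(point_mask_distance(pt, limb$mask, ct_l))
    }
    if (!is.null(tgt) && !is.null(limb)) {
      lt[j] <- mask_mask_distance(tgt$mask, limb$mask, ct_t, ct_l)
    }
  }
  data.frame(frame = seg$frame_index, t = seg$times,
             gaze_target = gt, gaze_limb = gl, limb_target = lt)
}
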