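#' Scene and acquisition configuration for synthetic trials
#'
#' Describes the simulated recording setup: frame geometry of the scene
#' camera, sampling rates of every modality, the pinhole focal length tying
#' pixel and angular gaze representations together, and the layout of the
#' target object, the resting gaze position and the limb entry path.
#'
#' The default mirrors the wearable setup the pipeline is designed for:
#' a 1920x1080 px scene camera at 25 fps, gaze at 100 Hz, a 100 Hz head
#' gyroscope, 148 Hz forearm accelerometry and 1926 Hz two-channel sEMG.
#' The default focal length is chosen so that 1 px corresponds to 0.72 mm
#' at a typical manipulation distance of 0.8 m (`f = 800/0.72 ~ 1111 px`)
#' and scales proportionally with `width` so that reduced-scale scenes keep
#' a consistent camera model.
#'
#' Object and gaze geometry defaults are expressed as fractions of the frame
#' so they remain valid at any resolution: the target disc sits right of
#' center at 0.72 x width, 0.44 x height with radius 0.0375 x width; gaze
#' rests at 0.19 x width, 0.39 x height; the limb enters from the bottom
#' edge. `desk_scene()` is a 320x180 px configuration used throughout the
#' tests and cohort analyses: small enough for fast mask rasterization while
#' keeping all printed pixel thresholds (20 px fixation, 5 px grasp, 100 px
#' saccade start) representable inside the frame.
#'
#' @param width,height frame size in px.
#' @param fps video frame rate (frames/s).
#' @param gaze_hz,gyro_hz,acc_hz,emg_hz sampling rates (Hz).
#' @param focal_px pinhole focal length in px.
#' @param target_center,target_radius target disc geometry (px, 0-based
#'   `c(x, y)` = `c(col, row)` coordinates).
#' @param gaze_start resting gaze position (px).
#' @param limb_base_x x position where the limb wedge meets the bottom edge
#'   (px); `limb_base_halfwidth` its half width at the base and
#'   `limb_tip_halfwidth` at the tip.
#' @param window analysis window in seconds relative to the end of the vocal
#'   instruction, `c(start, end)`.
#' @param gaze_depth_mm simulated gaze depth along the optical axis (mm).
#' @return A `vm_scene` list.
#' @examples
#' sc <- desk_scene()
#' sc$focal_px
#' @export
scene_config <- function(width = 1920L, height = 1080L, fps = 25,
                         gaze_hz = 100, gyro_hz = 100, acc_hz = 148,
                         emg_hz = 1926,
                         focal_px = (800 / 0.72) * width / 1920,
                         target_center = c(0.72 * width, 0.44 * height),
                         target_radius = 0.0375 * width,
                         gaze_start = c(0.19 * width, 0.39 * height),
                         limb_base_x = target_center[1] - 0.015 * width,
                         limb_base_halfwidth = 0.10 * height,
                         limb_tip_halfwidth = 0.045 * height,
                         window = c(-2, 2.5),
                         gaze_depth_mm = 800) {
  rates <- c(fps = fps, gaze_hz = gaze_hz, gyro_hz = gyro_hz,
             acc_hz = acc_hz, emg_hz = emg_hz)
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    stop("all sampling rates must be positive", call. = FALSE)
  }
  stopifnot(width >= 8, height >= 8, focal_px > 0, target_radius > 0,
            length(window) == 2L, window[1] < window[2], gaze_depth_mm > 0)
  if (target_center[1] - target_radius < 0 ||
      target_center[1] + target_radius > width - 1 ||
      target_center[2] - target_radius < 0 ||
      target_center[2] + target_radius > height - 1) {
    stop("target object must lie fully inside the frame", call. = FALSE)
  }
  if (gaze_start[2] >= height || gaze_start[1] >= width ||
      any(gaze_start < 0)) {
    stop("gaze start point must lie inside the frame", call. = FALSE)
  }
  structure(
    list(width = as.integer(width), height = as.integer(height), fps = fps,
         gaze_hz = gaze_hz, gyro_hz = gyro_hz, acc_hz = acc_hz,
         emg_hz = emg_hz, focal_px = focal_px,
         target_center = as.numeric(target_center),
         target_radius = as.numeric(target_radius),
         gaze_start = as.numeric(gaze_start),
         limb_base_x = as.numeric(limb_base_x),
         limb_base_halfwidth = as.numeric(limb_base_halfwidth),
         limb_tip_halfwidth = as.numeric(limb_tip_halfwidth),
         window = as.numeric(window),
         gaze_depth_mm = as.numeric(gaze_depth_mm)),
    class = "vm_scene"
  )
}

#' @rdname scene_config
#' @param ... overrides passed on to [scene_config()].
#' @export
desk_scene <- function(...) {
  scene_config(width = 320L, height = 180L, ...)
}

# px per degree of visual angle at the scene focal length (small-angle).
px_per_degree <- function(scene) scene$focal_px * pi / 180
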