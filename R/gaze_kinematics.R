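#' Interpolate short pupil gaps
#'
#' Linearly interpolates pupil coordinates across contiguous missing spans
#' that are strictly shorter than `max_gap` seconds and have valid samples
#' on both sides. The gap length is measured as the elapsed time between
#' the two surrounding valid samples; gaps of exactly `max_gap` or longer,
#' and gaps touching the series boundary, are left missing. Valid samples
#' are never modified.
#'
#' @param series a gaze data frame with strictly increasing `t` and pupil
#'   columns `plx, ply, plz, prx, pry, prz` (as produced by
#'   [synth_gaze()]); missingness is taken from `plx`/`prx` per side.
#' @param max_gap maximum (exclusive) gap duration in seconds.
#' @return The series with interpolatable gaps filled and `pupils_valid`
#'   updated.
#' @export
interpolate_pupils <- function(series, max_gap = 0.075) {
  t <- series$t
  if (any(diff(t) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  cols <- c("plx", "ply", "plz", "prx", "pry", "prz")
  miss <- is.na(series$plx) | is.na(series$prx)
  if (!any(miss)) return(series)
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  n <- length(t)
  for (k in which(r$values)) {
    a <- starts[k]; b <- ends[k]
    if (a == 1L || b == n) next           # boundary gap
    gap <- t[b + 1L] - t[a - 1L]
    if (gap >= max_gap) next              # strict threshold
    w <- (t[a:b] - t[a - 1L]) / gap
    for (cl in cols) {
      v0 <- series[[cl]][a - 1L]
      v1 <- series[[cl]][b + 1L]
      if (is.na(v0) || is.na(v1)) next
      series[[cl]][a:b] <- v0 + w * (v1 - v0)
    }
  }
  series$pupils_valid <- !(is.na(series$plx) | is.na(series$prx))
  series
}

#' Recenter the gaze point between the pupils
#'
#' Maps 3-D gaze points from scene-camera coordinates to a coordinate
#' system centred between the left and right pupils:
#' `g_hat = g - (p_left + p_right) / 2`, per coordinate. Missing pupil
#' coordinates propagate to the output.
#'
#' @param g numeric length-3 vector or `n x 3` matrix of gaze points (mm).
#' @param p_left,p_right pupil positions, same shape as `g`.
#' @return Recentered gaze, same shape as `g`; rows with any missing pupil
#'   coordinate are all-`NA`.
#' @examples
#' recenter_gaze(c(0, 0, 800), c(-30, 0, 0), c(30, 0, 0))
#' @export
recenter_gaze <- function(g, p_left, p_right) {
  vec <- is.null(dim(g))
  g <- rbind(g); p_left <- rbind(p_left); p_right <- rbind(p_right)
  out <- g - (p_left + p_right) / 2
  bad <- rowSums(is.na(p_left) | is.na(p_right)) > 0
  out[bad, ] <- NA_real_
  if (vec) out[1, ] else out
}

#' Angular difference between two 3-D vectors
#'
#' `arccos` of the normalized dot product, in degrees. The argument is
#' clamped to `[-1, 1]` so that numerically (anti)parallel vectors never
#' produce `NaN`. Zero-norm or missing vectors yield `NA` rather than an
#' error.
#'
#' @param a,b length-3 vectors, or `n x 3` matrices compared row-wise.
#' @return Angle(s) in degrees, in `[0, 180]`.
#' @examples
#' angular_difference(c(1, 0, 0), c(0, 1, 0)) # 90
#' angular_difference(c(1, 0, 0), c(1, 1, 0)) # 45
#' @export
angular_difference <- function(a, b) {
  vec <- is.null(dim(a)) && is.null(dim(b))
  a <- rbind(a); b <- rbind(b)
  na <- sqrt(rowSums(a * a))
  nb <- sqrt(rowSums(b * b))
  dot <- rowSums(a * b)
  denom <- na * nb
  out <- rep(NA_real_, length(dot))
  ok <- !is.na(denom) & denom > 0
  out[ok] <- acos(pmin(pmax(dot[ok] / denom[ok], -1), 1)) * 180 / pi
  if (vec) out[1] else out
}

#' Instantaneous angular gaze velocity
#'
#' Computes, for each sample `i >= 2`, the angular difference between the
#' recentered gaze vectors at `i - 1` and `i` divided by the time step:
#' `v_i = alpha_i / (t_i - t_{i-1})`, in deg/s. The first sample has no
#' velocity; samples whose own or preceding recentered gaze is missing get
#' `NA`.
#'
#' @param series gaze data frame with columns `t`, `gx, gy, gz` and pupil
#'   columns (run [interpolate_pupils()] first to limit missing data).
#' @return A data frame `t`, `velocity` aligned to the input timestamps.
#' @export
gaze_velocity <- function(series) {
  t <- series$t
  dt <- diff(t)
  if (any(dt == 0)) stop("duplicate timestamps", call. = FALSE)
  if (any(dt < 0)) stop("timestamps must be increasing", call. = FALSE)
  g <- cbind(series$gx, series$gy, series$gz)
  pl <- cbind(series$plx, series$ply, series$plz)
  pr <- cbind(series$prx, series$pry, series$prz)
  ghat <- recenter_gaze(g, pl, pr)
  n <- nrow(ghat)
  v <- rep(NA_real_, n)
  if (n >= 2) {
    alpha <- angular_difference(ghat[-n, , drop = FALSE],
                                ghat[-1, , drop = FALSE])
    v[-1] <- alpha / dt
  }
  data.frame(t = t, velocity = v)
}
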