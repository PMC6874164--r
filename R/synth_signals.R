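#' Synthesize head gyroscope, forearm accelerometer and sEMG streams
#'
#' Each generator plants a burst at the scheduled onset on top of rest
#' noise, shaped so that the corresponding detection rule fires at the
#' planted time:
#'
#' * `synth_gyro()`: 3-axis head angular velocity (deg/s). The norm stays
#'   well below the 12 deg/s head threshold before the head onset, then
#'   jumps to 1.5x the threshold and follows a half-sine burst
#'   (`gyro_peak`, `gyro_burst_s`).
#' * `synth_acc()`: 3-axis acceleration (g) around a constant ~1 g gravity
#'   orientation; the deviation from the rest orientation jumps to
#'   `acc_step` (default 0.10 g, above the 0.07 g arm threshold) at the arm
#'   onset, with a half-sine reach transient of amplitude `acc_peak`, and
#'   stays at the plateau afterwards (the arm does not return to its
#'   initial orientation).
#' * `synth_emg()`: two-channel sEMG ("mV", arbitrary units), extensor and
#'   flexor. Both are amplitude-modulated carriers: baseline gain 1 before
#'   the muscle onset, then a burst whose gain exceeds 4x baseline; the
#'   extensor burst starts at the onset, the flexor `emg_flexor_lag_s`
#'   later, so the extensor leads. With `emg_stochastic = FALSE` the
#'   carrier is a deterministic sinusoid with unit RMS, keeping the moving
#'   RMS envelope and rest baseline well defined on noiseless fixtures.
#'
#' @inheritParams synth_gaze
#' @return Data frames with column `t` plus `x, y, z` (gyro, acc) or
#'   `extensor, flexor` (sEMG).
#' @name synth-signals
NULL

signal_times <- function(scene, hz) {
  win <- scene$window
  seq(floor((win[1] - 0.08) * hz), ceiling((win[2] + 0.08) * hz)) / hz
}

#' @rdname synth-signals
#' @export
synth_gyro <- function(schedule, scene, profile, seed = NULL) {
  stopifnot(inherits(schedule, "vm_schedule"), inherits(scene, "vm_scene"))
  with_seed(seed, {
    t <- signal_times(scene, scene$gyro_hz)
    n <- length(t)
    t_h <- schedule$times[["head"]]
    peak <- profile$gyro_peak * stats::runif(1, 0.9, 1.1)
    u <- (t - t_h) / profile$gyro_burst_s
    burst <- ifelse(u >= 0 & u <= 1, 18 + (peak - 18) * sin(pi * u), 0)
    dir <- unit_vec(stats::rnorm(3))
    noise <- matrix(stats::rnorm(3 * n, 0, profile$gyro_noise), n, 3)
    sig <- outer(burst, dir) + noise
    data.frame(t = t, x = sig[, 1], y = sig[, 2], z = sig[, 3])
  })
}

#' @rdname synth-signals
#' @export
synth_acc <- function(schedule, scene, profile, seed = NULL) {
  stopifnot(inherits(schedule, "vm_schedule"), inherits(scene, "vm_scene"))
  with_seed(seed, {
    t <- signal_times(scene, scene$acc_hz)
    n <- length(t)
    t_a <- schedule$times[["arm"]]
    g0 <- unit_vec(c(0.15, -0.95, 0.27) + stats::rnorm(3, 0, 0.05))
    dir <- unit_vec(stats::rnorm(3))
    u <- (t - t_a) / profile$acc_rise_s
    dev <- ifelse(t >= t_a,
                  profile$acc_step +
                    profile$acc_peak * sin(pi * pmin(pmax(u, 0), 1)),
                  0)
    noise <- matrix(stats::rnorm(3 * n, 0, profile$acc_noise), n, 3)
    sig <- matrix(g0, n, 3, byrow = TRUE) + outer(dev, dir) + noise
    data.frame(t = t, x = sig[, 1], y = sig[, 2], z = sig[, 3])
  })
}

#' @rdname synth-signals
#' @export
synth_emg <- function(schedule, scene, profile, seed = NULL) {
  stopifnot(inherits(schedule, "vm_schedule"), inherits(scene, "vm_scene"))
  with_seed(seed, {
    t <- signal_times(scene, scene$emg_hz)
    n <- length(t)
    t_m <- schedule$times[["muscles"]]
    gain <- function(onset, pars, rise) {
      u <- (t - onset) / rise
      ifelse(t >= onset,
             pars[1] + (pars[2] - pars[1]) * sin(pi * pmin(pmax(u, 0), 1)),
             1)
    }
    g_ext <- gain(t_m, profile$emg_gain_ext, 0.5)
    g_flx <- gain(t_m + profile$emg_flexor_lag_s, profile$emg_gain_flex, 0.8)
    if (profile$emg_stochastic) {
      c_ext <- stats::rnorm(n)
      c_flx <- stats::rnorm(n)
    } else {
      c_ext <- sqrt(2) * sin(2 * pi * 150 * t)
      c_flx <- sqrt(2) * sin(2 * pi * 130 * t)
    }
    data.frame(t = t,
               extensor = profile$emg_noise_sd[1] * g_ext * c_ext,
               flexor = profile$emg_noise_sd[2] * g_flx * c_flx)
  })
}
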