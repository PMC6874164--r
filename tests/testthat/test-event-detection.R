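grid5 <- function(n) analysis_grid(c(-2, 2.5), 0.02)[seq_len(n)]

test_that("sustained-run primitives ignore single-bin outliers", {
  tm <- grid5(4)
  expect_equal(first_sustained_below(tm, c(30, 15, 16, 30), 20), tm[2])
  expect_true(is.na(first_sustained_below(grid5(3), c(30, 15, 30), 20)))
  expect_true(is.na(first_sustained_below(tm, rep(NA_real_, 4), 20)))
  # missing bins break runs
  expect_true(is.na(first_sustained_below(tm, c(30, 15, NA, 16), 20)))
  expect_equal(first_sustained_above(tm, c(5, 13, 14, 5), 12), tm[2])
  # strict comparison: values exactly at the threshold do not count
  expect_true(is.na(first_sustained_above(tm, c(12, 12, 12, 12), 12)))
})

test_that("saccade onset is the last slow bin with a distant start", {
  cfg <- detection_config()
  tm <- analysis_grid(cfg$window, cfg$grid_step)
  vel <- rep(NA_real_, length(tm))
  dist <- rep(150, length(tm))
  # velocity [40, 50, 90, 120, 100] ending right before fixation at bin 106
  vel[101:105] <- c(40, 50, 90, 120, 100)
  fix <- list(time = tm[106], status = "detected")
  ev <- detect_saccade(tm, vel, dist, fix, cfg)
  expect_equal(ev$time, tm[102])
  expect_equal(ev$status, "detected")

  # gaze-target distance below 100 px at the candidate bin: missing
  dist2 <- dist; dist2[102] <- 60
  expect_equal(detect_saccade(tm, vel, dist2, fix, cfg)$status, "missing")

  # missing velocity bins inside the burst do not displace the onset
  vel3 <- vel; vel3[103:104] <- NA
  expect_equal(detect_saccade(tm, vel3, dist, fix, cfg)$time, tm[102])

  # no fixation, no saccade
  expect_equal(detect_saccade(tm, vel, dist,
                              list(time = NA_real_, status = "missing"),
                              cfg)$status, "missing")
})

test_that("events inside the first 100 ms of the window are invalidated", {
  cfg <- detection_config()
  tm <- analysis_grid(cfg$window, cfg$grid_step)
  # distance below threshold from the very first bin
  d <- rep(30, length(tm)); d[1:10] <- 5
  ev <- detect_fixation(tm, d, cfg)
  expect_equal(ev$status, "invalid_early")
  expect_true(is.na(ev$time))
  # same for a gyro burst at the window start
  g <- rep(0, length(tm)); g[1:20] <- 40
  expect_equal(detect_head(tm, g, cfg)$status, "invalid_early")
  # never crossing: missing
  expect_equal(detect_head(tm, rep(5, length(tm)), cfg)$status, "missing")
})

test_that("muscle rule is a strict per-bin OR over channels", {
  cfg <- detection_config()
  tm <- analysis_grid(cfg$window, cfg$grid_step)[101:108]
  base <- c(extensor = 0.02, flexor = 0.01)
  ext <- rep(0.02, 8); flx <- rep(0.01, 8)
  # extensor-only burst detected
  ext2 <- ext; ext2[4:6] <- 0.1
  ev <- detect_muscles(tm, list(extensor = ext2, flexor = flx), base, cfg)
  expect_equal(ev$time, tm[4])
  # both channels at exactly 4x: strict >, not detected
  ev2 <- detect_muscles(tm, list(extensor = rep(0.08, 8),
                                 flexor = rep(0.04, 8)), base, cfg)
  expect_equal(ev2$status, "missing")
  # alternating channels still satisfy the per-bin OR
  ext3 <- ext; ext3[4] <- 0.1
  flx3 <- flx; flx3[5] <- 0.05
  ev3 <- detect_muscles(tm, list(extensor = ext3, flexor = flx3), base, cfg)
  expect_equal(ev3$time, tm[4])
  # no baseline: undetectable
  expect_equal(detect_muscles(tm, list(extensor = ext2, flexor = flx),
                              NULL, cfg)$status, "undetectable")
})

test_that("noiseless planted events are recovered within one grid step", {
  tr <- noiseless_trial(seed = 5)
  ev <- detect_events(tr)
  expect_true(all(ev$status == "detected"))
  planted <- tr$schedule$times[ev$event]
  expect_true(all(abs(ev$time - planted) <= 0.02 + 1e-9))
  # detected ordering respects the planted design
  tt <- setNames(ev$time, ev$event)
  expect_lte(tt[["saccade"]], tt[["fixation"]])
  expect_lt(tt[["fixation"]], tt[["grasp"]])
})

test_that("missing streams mark only their events undetectable", {
  tr <- noiseless_trial(seed = 6)
  tr$acc <- NULL
  ev <- detect_events(tr)
  expect_equal(ev$status[ev$event == "arm"], "undetectable")
  expect_true(all(ev$status[ev$event %in%
                              c("fixation", "saccade", "head",
                                "muscles", "grasp")] == "detected"))
  tr2 <- noiseless_trial(seed = 6)
  tr2$emg <- NULL
  ev2 <- detect_events(tr2)
  expect_equal(ev2$status[ev2$event == "muscles"], "undetectable")
  expect_equal(ev2$status[ev2$event == "arm"], "detected")
})

test_that("fixation time is monotone in the distance threshold", {
  # shrinking the threshold never makes the event earlier; growing it
  # never makes it later (when detected in both)
  tr <- noiseless_trial(seed = 7)
  f <- trial_features(tr)
  times <- vapply(c(5, 10, 20, 40, 80), function(thr) {
    detect_fixation(f$time, f$gaze_target,
                    detection_config(fixation_px = thr))$time
  }, numeric(1))
  ok <- !is.na(times)
  expect_true(all(diff(times[ok]) <= 1e-9))
})

test_that("halving the grid step moves noiseless events by at most one coarse bin", {
  tr <- noiseless_trial(seed = 8)
  ev1 <- detect_events(tr, detection_config(grid_step = 0.02))
  ev2 <- detect_events(tr, detection_config(grid_step = 0.01))
  both <- ev1$status == "detected" & ev2$status == "detected"
  expect_true(any(both))
  expect_true(all(abs(ev1$time[both] - ev2$time[both]) <= 0.02 + 1e-9))
})

test_that("default configuration carries the published thresholds", {
  cfg <- detection_config()
  expect_equal(cfg$fixation_px, 20)
  expect_equal(cfg$saccade_deg_s, 70)
  expect_equal(cfg$head_deg_s, 12)
  expect_equal(cfg$arm_g, 0.07)
  expect_equal(cfg$muscle_multiplier, 4)
  expect_equal(cfg$grasp_px, 5)
  expect_equal(cfg$window, c(-2, 2.5))
  expect_equal(cfg$grid_step, 0.02)
  expect_equal(cfg$successive, 2L)
})
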