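test_that("point-mass schedules are exact and seeded draws reproducible", {
  p <- point_profile(saccade = -0.3, fixation = -0.15, grasp = 0.45)
  s <- sample_schedule(p, seed = 1)
  expect_equal(s$times[["saccade"]], -0.3)
  expect_equal(s$times[["fixation"]], -0.15)
  expect_equal(s$times[["grasp"]], 0.45)

  pi_ <- intact_profile()
  s1 <- sample_schedule(pi_, seed = 123)
  s2 <- sample_schedule(pi_, seed = 123)
  expect_identical(s1, s2)
  expect_false(identical(s1$times,
                         sample_schedule(pi_, seed = 124)$times))
})

test_that("schedule draws respect ordering and window constraints", {
  pa <- amputated_profile()
  set.seed(10)
  for (i in 1:200) {
    s <- sample_schedule(pa)
    tt <- s$times
    expect_lt(tt[["saccade"]], tt[["fixation"]])
    if (!is.na(tt[["grasp"]])) expect_lt(tt[["fixation"]], tt[["grasp"]])
    present <- tt[!is.na(tt)]
    expect_true(all(present > -1.9) && all(present < 2.5))
  }
  # unsatisfiable ordering errors out with a helpful message
  bad <- timing_profile(saccade_to_fixation = dist_point(-0.2))
  expect_error(sample_schedule(bad, seed = 2, max_tries = 50),
               "saccade_to_fixation")
})

test_that("planted interval medians match the configured distributions", {
  p <- intact_profile()
  set.seed(77)
  draws <- replicate(10000, NA_real_)
  i <- 0
  while (i < 10000) {
    s <- sample_schedule(p)
    if (is.na(s$times[["grasp"]])) next
    i <- i + 1
    draws[i] <- s$times[["grasp"]] - s$times[["fixation"]]
  }
  # rejection of out-of-order / out-of-window draws biases the planted
  # median upward by < 25 ms relative to the configured 561 ms
  expect_equal(median(draws), 0.561, tolerance = 0.05)
  direct <- sample_dist(p$fixation_to_grasp, 20000)
  expect_equal(median(draws), median(direct[direct > 0]), tolerance = 0.02)
})

test_that("noiseless gaze converges monotonically and crosses 70 deg/s", {
  sc <- desk_scene()
  tr <- noiseless_trial(seed = 9, scene = sc)
  s <- tr$schedule$times
  g <- tr$gaze
  dd <- sqrt((g$fx - sc$target_center[1])^2 + (g$fy - sc$target_center[2])^2)
  inflight <- g$t >= s[["saccade"]] & g$t <= s[["fixation"]]
  expect_true(all(diff(dd[inflight]) <= 1e-9))
  vel <- gaze_velocity(g)
  expect_gt(max(vel$velocity[inflight], na.rm = TRUE), 70)
  # 3-D / 2-D consistency under the pinhole model
  ghat <- recenter_gaze(cbind(g$gx, g$gy, g$gz),
                        cbind(g$plx, g$ply, g$plz),
                        cbind(g$prx, g$pry, g$prz))
  fx <- (sc$width - 1) / 2 + sc$focal_px * ghat[, 1] / ghat[, 3]
  fy <- (sc$height - 1) / 2 + sc$focal_px * ghat[, 2] / ghat[, 3]
  expect_equal(fx, g$fx, tolerance = 1e-9)
  expect_equal(fy, g$fy, tolerance = 1e-9)
})

test_that("gaze synthesis rejects start points closer than 100 px", {
  sc <- desk_scene()
  near <- desk_scene(gaze_start = sc$target_center - c(60, 0))
  p <- point_profile()
  s <- sample_schedule(p, seed = 1)
  expect_error(synth_gaze(s, near, p), "100 px")
})

test_that("low-accuracy trials never approach the target mask", {
  p <- intact_profile(low_accuracy_fraction = 1)
  sc <- desk_scene()
  tr <- generate_trial(p, sc, seed = 21)
  expect_true(tr$schedule$low_accuracy)
  ds <- distance_series(tr)
  expect_gt(min(ds$gaze_target, na.rm = TRUE), 20)
})

test_that("masks realize contact, stop-short and selection fixtures", {
  sc <- desk_scene()
  tr <- noiseless_trial(seed = 11, scene = sc)
  ds <- distance_series(tr)
  t_g <- tr$schedule$times[["grasp"]]
  expect_lt(min(abs(ds$limb_target[ds$t >= t_g]), na.rm = TRUE), 5)

  # amputated stop-short trial: limb never reaches the configured offset
  pa <- point_profile(base = amputated_profile())
  pa$touch_fraction <- 0
  eff <- list(onset = 0, saccade_to_fixation = 0, saccade_to_head = 0,
              head_to_arm = 0, arm_to_muscles = 0, fixation_to_grasp = 0,
              stop_short_px = 30)
  tra <- generate_trial(pa, sc, seed = 12, effects = eff)
  expect_false(tra$schedule$touch)
  dsa <- distance_series(tra)
  expect_gte(min(dsa$limb_target, na.rm = TRUE), tra$schedule$stop_short_px)
  grasp_ev <- detect_events(tra)
  expect_equal(grasp_ev$status[grasp_ev$event == "grasp"], "missing")

  # distractor instances exercise the tie-break and score rules
  trd <- generate_trial(point_profile(), sc, seed = 13, distractors = TRUE)
  fr <- trd$frames$frames[[1]]
  classes <- vapply(fr, `[[`, character(1), "class")
  tc <- trd$meta$target_class
  expect_gte(sum(classes == tc), 2)
  sel <- select_target(fr, tc)
  areas <- vapply(fr[classes == tc], `[[`, numeric(1), "area")
  scores <- vapply(fr[classes == tc], `[[`, numeric(1), "score")
  expect_equal(sel$area, max(areas[scores >= 0.8]))
})

test_that("pre-onset signals stay under the detection thresholds", {
  tr <- noiseless_trial(seed = 14)
  s <- tr$schedule$times
  gy <- tr$gyro
  pre <- gy$t < s[["head"]]
  expect_true(all(sqrt(gy$x^2 + gy$y^2 + gy$z^2)[pre] < 12))
  acc <- normalize_acc(tr$acc)
  pre_a <- acc$deviation$t < s[["arm"]]
  expect_true(all(acc$deviation$norm[pre_a] < 0.07))
  post_a <- acc$deviation$t > s[["arm"]] + 0.01
  expect_true(all(acc$deviation$norm[post_a] > 0.07))
  env <- emg_envelope(tr$emg)
  base <- emg_baseline(env)
  post_m <- env$t > s[["muscles"]] + 0.05 & env$t < s[["muscles"]] + 0.4
  expect_true(all(env$extensor[post_m] / base[["extensor"]] > 4))
  pre_m <- env$t < s[["muscles"]] - 0.05
  expect_true(all(env$extensor[pre_m] / base[["extensor"]] < 4))
  # extensor burst leads the flexor burst
  t_flex_on <- min(env$t[env$flexor > 4 * base[["flexor"]]])
  t_ext_on <- min(env$t[env$extensor > 4 * base[["extensor"]]])
  expect_lt(t_ext_on, t_flex_on)
})

test_that("cohorts have the planned size and are seed-reproducible", {
  p <- intact_profile()
  co <- generate_cohort(2, 3, p, desk_scene(), seed = 5)
  expect_length(co$trials, 6)
  expect_equal(nrow(co$plan$table), 6)
  expect_length(co$plan$effects, 2)
  co2 <- generate_cohort(2, 3, p, desk_scene(), seed = 5)
  expect_identical(co$trials, co2$trials)
  expect_error(generate_cohort(0, 3, p), "positive")
})

test_that("noiseless end-to-end pipeline recovers each onset in its bin", {
  # three different schedules, all on the frame lattice
  cases <- list(
    c(-0.28, -0.12, -0.26, -0.14, -0.06, 0.44),
    c(-0.52, -0.32, -0.48, -0.36, -0.28, 0.60),
    c(-0.80, -0.60, -0.84, -0.52, -0.60, 0.08)
  )
  for (cs in cases) {
    p <- point_profile(cs[1], cs[2], cs[3], cs[4], cs[5], cs[6])
    tr <- generate_trial(p, desk_scene(), seed = 99)
    ev <- detect_events(tr)
    expect_true(all(ev$status == "detected"))
    expect_true(all(abs(ev$time - tr$schedule$times[ev$event]) <=
                      0.02 + 1e-9),
                label = paste(cs, collapse = ","))
  }
})
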