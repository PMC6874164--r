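mk_inst <- function(class, score, mask, frame = 0L) {
  structure(list(class = class, score = score, mask = mask, frame = frame,
                 area = sum(mask)), class = "vm_instance")
}

disc <- function(cx, cy, r, w = 40, h = 40) {
  outer((0:(h - 1) - cy)^2, (0:(w - 1) - cx)^2, "+") <= r^2
}

test_that("target selection prefers large, confident instances", {
  big <- mk_inst("can", 0.9, disc(10, 10, 8))
  small <- mk_inst("can", 0.95, disc(30, 30, 5))
  other <- mk_inst("mug", 0.99, disc(20, 20, 10))
  expect_identical(select_target(list(small, big, other), "can"), big)
  # score below 0.8 is ignored
  low <- mk_inst("can", 0.79, disc(10, 10, 8))
  expect_null(select_target(list(low), "can"))
  expect_identical(select_target(list(low, small), "can"), small)
  # equal areas: deterministic tie-break on the lowest instance index
  a <- mk_inst("can", 0.9, disc(10, 10, 6))
  b <- mk_inst("can", 0.9, disc(28, 28, 6))
  expect_equal(a$area, b$area)
  expect_identical(select_target(list(a, b), "can"), a)
  expect_null(select_target(list(), "can"))
})

test_that("limb selection requires a centroid strictly in the lower half", {
  h <- 40
  lower <- mk_inst("person", 0.9, disc(20, 0.8 * h, 6, h = h))
  upper <- mk_inst("person", 0.9, disc(20, 0.2 * h, 6, h = h))
  expect_identical(select_limb(list(upper, lower), h), lower)
  expect_null(select_limb(list(upper), h))
  # centroid exactly at h/2 is excluded
  m <- matrix(FALSE, h, 40); m[(h / 2 - 1):(h / 2 + 3), 10] <- TRUE
  mid <- mk_inst("person", 0.9, m)
  rows <- which(rowSums(m) > 0) - 1
  expect_equal(mean(rows), h / 2)
  expect_null(select_limb(list(mid), h))
  # low score ignored even in the lower half
  lowsc <- mk_inst("person", 0.5, disc(20, 0.8 * h, 6, h = h))
  expect_null(select_limb(list(lowsc), h))
})

test_that("contour extraction matches counting and the exhaustive oracle", {
  m1 <- matrix(FALSE, 5, 5); m1[3, 3] <- TRUE
  expect_equal(unname(mask_contour(m1)), cbind(2L, 2L))

  # filled 10x10 square: 36 perimeter pixels
  sq <- matrix(FALSE, 14, 14); sq[3:12, 3:12] <- TRUE
  expect_equal(nrow(mask_contour(sq)), 36)

  # fully set 4x4 frame: the 12 edge pixels form the contour
  full <- matrix(TRUE, 4, 4)
  expect_equal(nrow(mask_contour(full)), 12)

  set.seed(5)
  for (i in 1:8) {
    m <- random_blob(20, 24)
    got <- mask_contour(m)
    want <- oracle_contour(m)
    expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
                 unname(want[order(want[, 1], want[, 2]), , drop = FALSE]),
                 ignore_attr = TRUE)
  }
  expect_error(mask_contour(matrix(FALSE, 3, 3)), "empty")
})

test_that("point-mask distance is 0 on overlap and exact off it", {
  m <- matrix(FALSE, 10, 10); m[4:6, 4:6] <- TRUE
  expect_equal(as.numeric(point_mask_distance(c(4, 4), m)), 0)
  # single pixel at (x=4, y=3) from the origin: 3-4-5 triangle
  m2 <- matrix(FALSE, 10, 10); m2[4, 5] <- TRUE
  expect_equal(as.numeric(point_mask_distance(c(0, 0), m2)), 5)
  # outside-frame points are computed and flagged
  d <- point_mask_distance(c(-3, 0), m2)
  expect_true(attr(d, "outside_frame"))
  expect_equal(as.numeric(d), sqrt(7^2 + 3^2))

  set.seed(11)
  for (i in 1:8) {
    m <- random_blob(18, 18)
    p <- runif(2, 0, 17)
    got <- as.numeric(point_mask_distance(p, m))
    pr <- round(p)
    if (m[pr[2] + 1, pr[1] + 1]) {
      expect_equal(got, 0)
    } else {
      # disjoint case: brute force over all mask pixels; for a point
      # outside the mask the nearest mask pixel is a boundary pixel
      expect_equal(got, oracle_point_distance(p, m))
    }
  }
})

test_that("mask-mask distance is exact, symmetric and dilation-monotone", {
  a <- matrix(FALSE, 12, 12); a[2:4, 2:4] <- TRUE
  b <- matrix(FALSE, 12, 12); b[3:6, 3:6] <- TRUE
  expect_equal(mask_mask_distance(a, b), 0)
  # single pixels at (0,0) and (x=6, y=8): 6-8-10
  p1 <- matrix(FALSE, 12, 12); p1[1, 1] <- TRUE
  p2 <- matrix(FALSE, 12, 12); p2[9, 7] <- TRUE
  expect_equal(mask_mask_distance(p1, p2), 10)
  expect_error(mask_mask_distance(p1, matrix(FALSE, 12, 12)), "empty")

  dilate <- function(m) {
    h <- nrow(m); w <- ncol(m); out <- m
    out[-1, ] <- out[-1, ] | m[-h, ]; out[-h, ] <- out[-h, ] | m[-1, ]
    out[, -1] <- out[, -1] | m[, -w]; out[, -w] <- out[, -w] | m[, -1]
    out
  }
  set.seed(13)
  for (i in 1:8) {
    ma <- random_blob(22, 22, 2)
    mb <- random_blob(22, 22, 2)
    d <- mask_mask_distance(ma, mb)
    expect_equal(d, mask_mask_distance(mb, ma))
    if (!any(ma & mb)) {
      expect_equal(d, oracle_mask_distance(ma, mb))
    } else {
      expect_equal(d, 0)
    }
    expect_lte(mask_mask_distance(dilate(ma), mb), d)
    expect_lte(mask_mask_distance(ma, dilate(mb)), d)
  }
})

test_that("the per-trial distance series reflects the planted geometry", {
  tr <- noiseless_trial(seed = 3)
  ds <- distance_series(tr)
  t_g <- tr$schedule$times[["grasp"]]
  at_grasp <- which.min(abs(ds$t - t_g))
  expect_lt(ds$limb_target[at_grasp], 5)
  # before arm onset there is no person instance: limb distances missing
  pre <- ds$t < tr$schedule$times[["arm"]] - 0.05
  expect_true(all(is.na(ds$limb_target[pre])))
  expect_true(all(is.na(ds$gaze_limb[pre])))
  # gaze-target defined everywhere (target always present)
  expect_true(all(!is.na(ds$gaze_target)))

  # a trial with no person instances at all: strip them
  tr2 <- tr
  tr2$frames$frames <- lapply(tr2$frames$frames, function(fr) {
    Filter(function(i) i$class != "person", fr)
  })
  ds2 <- distance_series(tr2)
  expect_true(all(is.na(ds2$gaze_limb)))
  expect_true(all(is.na(ds2$limb_target)))
  expect_false(all(is.na(ds2$gaze_target)))
})
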