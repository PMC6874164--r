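# Shared fixtures: deterministic profiles and small random mask generators.

# Point-mass profile with all planted times on the 40 ms frame lattice, so
# frame-rate quantization cannot displace detected events by more than one
# 20 ms grid bin.
point_profile <- function(saccade = -0.28, fixation = -0.12, head = -0.26,
                          arm = -0.14, muscles = -0.06, grasp = 0.44,
                          base = intact_profile()) {
  noiseless_profile(timing_profile(
    group = base$group,
    saccade_onset = dist_point(saccade),
    saccade_to_fixation = dist_point(fixation - saccade),
    saccade_to_head = dist_point(head - saccade),
    head_to_arm = dist_point(arm - head),
    arm_to_muscles = dist_point(muscles - arm),
    fixation_to_grasp = dist_point(grasp - fixation),
    touch_fraction = base$touch_fraction
  ))
}

noiseless_trial <- function(seed = 42, scene = desk_scene(), ...) {
  generate_trial(point_profile(...), scene, seed = seed)
}

# Random blob mask: union of a few filled discs, guaranteed nonempty.
random_blob <- function(h, w, n_discs = 3) {
  m <- matrix(FALSE, h, w)
  for (i in seq_len(n_discs)) {
    cx <- stats::runif(1, 0, w - 1)
    cy <- stats::runif(1, 0, h - 1)
    r <- stats::runif(1, 1, max(2, min(h, w) / 4))
    dy2 <- (0:(h - 1) - cy)^2
    dx2 <- (0:(w - 1) - cx)^2
    m <- m | (outer(dy2, dx2, "+") <= r^2)
  }
  if (!any(m)) m[sample(h, 1), sample(w, 1)] <- TRUE
  m
}

# Brute-force oracles -------------------------------------------------------

# boundary pixels by exhaustive neighbour testing
oracle_contour <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  out <- NULL
  for (r in seq_len(h)) {
    for (cl in seq_len(w)) {
      if (!mask[r, cl]) next
      boundary <- FALSE
      for (dr in -1:1) {
        for (dc in -1:1) {
          if (dr == 0 && dc == 0) next
          rr <- r + dr; cc <- cl + dc
          if (rr < 1 || rr > h || cc < 1 || cc > w || !mask[rr, cc]) {
            boundary <- TRUE
          }
        }
      }
      if (boundary) out <- rbind(out, c(r - 1L, cl - 1L))
    }
  }
  out
}

# min distance between all pixel pairs of two disjoint masks
oracle_mask_distance <- function(a, b) {
  pa <- which(a, arr.ind = TRUE) - 1L
  pb <- which(b, arr.ind = TRUE) - 1L
  best <- Inf
  for (i in seq_len(nrow(pa))) {
    d2 <- (pb[, 1] - pa[i, 1])^2 + (pb[, 2] - pa[i, 2])^2
    best <- min(best, min(d2))
  }
  sqrt(best)
}

oracle_point_distance <- function(point, mask) {
  p <- which(mask, arr.ind = TRUE) - 1L
  sqrt(min((p[, 2] - point[1])^2 + (p[, 1] - point[2])^2))
}

oracle_moving_rms <- function(x, window) {
  n <- length(x)
  half <- (window - 1) %/% 2
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    sqrt(mean(x[lo:hi]^2))
  }, numeric(1))
}

oracle_bin_mean <- function(t, x, grid, step) {
  vapply(grid, function(g) {
    sel <- t >= g - step / 2 & t < g + step / 2 & !is.na(x)
    if (!any(sel)) NA_real_ else mean(x[sel])
  }, numeric(1))
}

# sup ECDF difference by sweeping all sample points
oracle_ks_stat <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(vapply(pts, function(p) abs(mean(a <= p) - mean(b <= p)), numeric(1)))
}

oracle_gaze_velocity <- function(series) {
  n <- nrow(series)
  v <- rep(NA_real_, n)
  for (i in 2:n) {
    pm1 <- c(series$plx[i - 1], series$ply[i - 1], series$plz[i - 1])
    pm2 <- c(series$prx[i - 1], series$pry[i - 1], series$prz[i - 1])
    qm1 <- c(series$plx[i], series$ply[i], series$plz[i])
    qm2 <- c(series$prx[i], series$pry[i], series$prz[i])
    if (anyNA(c(pm1, pm2, qm1, qm2))) next
    g0 <- c(series$gx[i - 1], series$gy[i - 1], series$gz[i - 1]) - (pm1 + pm2) / 2
    g1 <- c(series$gx[i], series$gy[i], series$gz[i]) - (qm1 + qm2) / 2
    cosv <- sum(g0 * g1) / (sqrt(sum(g0^2)) * sqrt(sum(g1^2)))
    alpha <- acos(min(max(cosv, -1), 1)) * 180 / pi
    v[i] <- alpha / (series$t[i] - series$t[i - 1])
  }
  v
}

# random gaze series with controllable missingness
random_gaze_series <- function(n = 60, hz = 100, miss = 0) {
  t <- seq_len(n) / hz
  g <- matrix(stats::rnorm(3 * n, c(0, 0, 800), 50), n, 3, byrow = FALSE)
  pl <- matrix(stats::rnorm(3 * n, c(-30, 25, -35), 2), n, 3)
  pr <- matrix(stats::rnorm(3 * n, c(30, 25, -35), 2), n, 3)
  df <- data.frame(t = t, gx = g[, 1], gy = g[, 2], gz = g[, 3],
                   plx = pl[, 1], ply = pl[, 2], plz = pl[, 3],
                   prx = pr[, 1], pry = pr[, 2], prz = pr[, 3],
                   fx = 0, fy = 0, pupils_valid = TRUE)
  if (miss > 0) {
    idx <- sample(2:(n - 1), ceiling(miss * n))
    df[idx, c("plx", "ply", "plz", "prx", "pry", "prz")] <- NA_real_
    df$pupils_valid[idx] <- FALSE
  }
  df
}
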