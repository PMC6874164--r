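events_row <- function(subject, trial, event, time, status = "detected",
                       group = "intact") {
  data.frame(subject = subject, group = group, trial = trial, event = event,
             time = time, status = status, stringsAsFactors = FALSE)
}

test_that("intervals are signed differences of detected endpoints", {
  ev <- rbind(
    events_row("S1", 1, "fixation", 0.10),
    events_row("S1", 1, "grasp", 0.66),
    events_row("S1", 1, "arm", 0.30),
    events_row("S1", 1, "muscles", 0.28),
    events_row("S1", 1, "saccade", NA, status = "missing"),
    events_row("S1", 1, "head", 0.05),
    events_row("S1", 2, "fixation", 0.2),
    events_row("S1", 2, "grasp", NA, status = "missing")
  )
  iv <- compute_intervals(ev)
  g <- function(nm, trial) iv$value[iv$interval == nm & iv$trial == trial]
  expect_equal(g("fixation -> grasp", 1), 0.56)
  expect_equal(g("arm -> muscles", 1), -0.02) # negative intervals allowed
  expect_true(is.na(g("saccade -> fixation", 1)))
  expect_true(is.na(g("fixation -> grasp", 2)))
  expect_equal(sort(unique(iv$interval)),
               sort(c("fixation -> grasp", "saccade -> fixation",
                      "saccade -> head", "head -> arm", "arm -> muscles")))
})

test_that("quartile summaries match the sort-based convention", {
  s <- quartile_summary(c(1, 2, 3, 4, 5))
  expect_equal(unname(s), c(5, 2, 3, 4))
  expect_equal(unname(quartile_summary(7)), c(1, 7, 7, 7))
  set.seed(3)
  x <- rnorm(101)
  s2 <- quartile_summary(x)
  xs <- sort(x)
  # type-7 linear interpolation between order statistics, by hand
  byhand <- function(p) {
    h <- (length(xs) - 1) * p + 1
    xs[floor(h)] + (h - floor(h)) * (xs[ceiling(h)] - xs[floor(h)])
  }
  expect_equal(unname(s2), c(101, byhand(0.25), byhand(0.5), byhand(0.75)))
  # permutation and shift invariance
  expect_equal(quartile_summary(sample(x)), s2)
  s3 <- quartile_summary(x + 10)
  expect_equal(unname(s3[-1]), unname(s2[-1]) + 10)
})

test_that("KS comparison equals the ECDF sweep oracle and is invariant", {
  expect_equal(ks_group_test(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(ks_group_test(c(0, 0, 0), c(1, 1, 1))$statistic, 1)
  set.seed(6)
  for (i in 1:6) {
    a <- rnorm(12)
    b <- rnorm(9, mean = 0.5)
    ks <- ks_group_test(a, b)
    expect_equal(ks$statistic, oracle_ks_stat(a, b))
    # invariant under a strictly monotone transform of both samples
    ks2 <- ks_group_test(exp(a), exp(b))
    expect_equal(ks2$statistic, ks$statistic)
    expect_equal(ks2$p_value, ks$p_value)
  }
  # asymptotic p-value at the effective sample size, against the closed form
  a <- c(0.1, 0.5, 0.9, 1.4); b <- c(0.3, 0.7, 1.1)
  ks <- ks_group_test(a, b)
  neff <- sqrt(4 * 3 / 7)
  x <- neff * ks$statistic
  pk <- 2 * sum((-1)^(1:100 - 1) * exp(-2 * (1:100)^2 * x^2))
  expect_equal(ks$p_value, min(1, max(0, pk)), tolerance = 1e-6)
  expect_error(ks_group_test(1, c(1, 2)), "two subjects")
})

test_that("engagement rate counts trials that ever come within threshold", {
  expect_equal(engagement_rate(c(0, 3, 19.9)), 1)
  expect_equal(engagement_rate(c(25, 40, NA)), 0)
  expect_equal(engagement_rate(c(2, 30, 10, 50)), 0.5)
})

test_that("profile aggregation omits mostly-missing bins and matches quantiles", {
  tm <- analysis_grid(c(-1, 1), 0.02)
  nb <- length(tm)
  # identical trials: all three summary lines equal the trial values
  row <- sin(seq_len(nb) / 10)
  mat <- matrix(row, 20, nb, byrow = TRUE)
  pr <- profile_aggregate(mat, tm)
  expect_equal(pr$median, row)
  expect_equal(pr$q1, row)
  expect_equal(pr$q3, row)
  # a bin missing in 95% of trials is omitted
  mat2 <- mat
  mat2[1:19, 5] <- NA
  pr2 <- profile_aggregate(mat2, tm)
  expect_true(pr2$omitted[5])
  expect_true(is.na(pr2$median[5]))
  expect_false(pr2$omitted[6])
  # random per-bin quantiles match stats::quantile on the non-missing values
  set.seed(12)
  mat3 <- matrix(rnorm(20 * nb), 20, nb)
  mat3[sample(length(mat3), 100)] <- NA
  pr3 <- profile_aggregate(mat3, tm)
  j <- 17
  v <- mat3[, j][!is.na(mat3[, j])]
  expect_equal(pr3$median[j], unname(quantile(v, 0.5, type = 7)))
  expect_equal(pr3$q1[j], unname(quantile(v, 0.25, type = 7)))
  expect_true(all(pr3$q1 <= pr3$median & pr3$median <= pr3$q3, na.rm = TRUE))
})

test_that("task categories follow the protocol table", {
  expect_equal(category_assign("Drink from the can"), "lifting")
  expect_equal(category_assign("Squeeze the clothespin"), "in place")
  expect_equal(category_assign("Move the ball to the right and back"),
               "displacement")
  expect_equal(category_assign("whatever", task_type = "static"), "static")
  expect_warning(out <- category_assign("Juggle the plates"), "unknown")
  expect_true(is.na(out))
  expect_equal(nrow(task_categories()), 20)
  expect_length(object_classes(), 18)
})

test_that("interval report assembles per-group quartiles and KS", {
  set.seed(44)
  mk <- function(subjects, group, med) {
    do.call(rbind, lapply(subjects, function(s) {
      data.frame(subject = s, group = group, trial = 1:20,
                 interval = "fixation -> grasp",
                 value = rlnorm(20, log(med), 0.3),
                 stringsAsFactors = FALSE)
    }))
  }
  iv <- rbind(mk(paste0("C", 1:6), "intact", 0.56),
              mk(paste0("A", 1:5), "amputated", 1.05))
  rep <- interval_report(iv)
  row <- rep[rep$interval == "fixation -> grasp", ]
  expect_equal(row$n_a, 120)
  expect_equal(row$n_b, 100)
  expect_equal(row$median_a, 0.56, tolerance = 0.15)
  expect_gt(row$median_b, row$median_a)
  expect_lte(row$p, 0.05) # clearly separated groups
  expect_true(all(c("fixation -> grasp", "arm -> muscles") %in% rep$interval))
})
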