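# Microstructure: interpolation, motion classification against the
# stated thresholds, pause detection rules, zone clustering, RT
# summaries and session metrics. Ground-truth comparisons use the
# synthetic generator at low noise.

test_that("interpolation fills gaps linearly and handles edges", {
  tr <- tracking_trace((1:3) / 30, c(0, 99, 2), valid = c(TRUE, FALSE, TRUE))
  out <- interpolate_gaps(tr)
  expect_equal(out$x_cm, c(0, 1, 2))
  expect_true(all(out$valid))
  # identity on all-valid traces
  tr2 <- tracking_trace((1:5) / 30, 1:5)
  expect_identical(interpolate_gaps(tr2), tr2)
  # leading/trailing invalid take nearest valid
  tr3 <- tracking_trace((1:4) / 30, c(99, 5, 7, 99),
                        valid = c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(interpolate_gaps(tr3)$x_cm, c(5, 5, 7, 7))
  expect_error(interpolate_gaps(
    tracking_trace((1:3) / 30, c(1, 9, 9),
                   valid = c(TRUE, FALSE, FALSE))), "unusable")
})

test_that("interpolation error on a smooth ramp is curvature-bounded", {
  # oracle: for f(t) = sin(t), linear interpolation over a gap of width
  # h has error <= h^2/8 * max|f''| = h^2/8
  set.seed(13)
  tm <- seq(0, 10, by = 1 / 30)
  xf <- 40 + 30 * sin(tm)
  drop <- sample(2:(length(tm) - 1), round(0.1 * length(tm)))
  valid <- !(seq_along(tm) %in% drop)
  tr <- tracking_trace(tm, ifelse(valid, xf, 999), valid = valid)
  out <- interpolate_gaps(tr)
  # max gap width in seconds
  gaps <- rle(!valid)
  h_max <- (max(gaps$lengths[gaps$values]) + 1) / 30
  bound <- h_max^2 / 8 * 30 # max |d2x/dt2| = 30
  expect_lt(max(abs(out$x_cm - xf)), bound + 1e-9)
})

test_that("motion classification obeys the stated thresholds", {
  fps <- 30; dt <- 1 / fps
  # constant x for 4 frames (3 still steps, 100 ms >= 90 ms) then a
  # monotone +2 cm run -> one qualifying pause then toward_goal
  x <- c(rep(10, 4), 10 + cumsum(rep(0.5, 4)))
  tr <- tracking_trace(seq_along(x) * dt, x)
  seg <- classify_motion(tr)
  expect_equal(seg$state, c("paused", "toward_goal"))
  expect_true(seg$qualifies[1])
  # stillness for only 2 frames (1 still step, 33 ms) -> no pause
  x2 <- c(seq(2, 10, by = 0.5), rep(10.01, 2), seq(10.5, 20, by = 0.5))
  tr2 <- tracking_trace(seq_along(x2) * dt, x2)
  seg2 <- classify_motion(tr2)
  expect_false(any(seg2$qualifies))
  # movement below 1.5 cm is jitter, absorbed into the pause
  x3 <- c(rep(10, 5), 10.4, rep(10.4, 4), seq(11, 20, by = 0.5))
  tr3 <- tracking_trace(seq_along(x3) * dt, x3)
  seg3 <- classify_motion(tr3)
  expect_equal(sum(seg3$state == "paused"), 1)
})

test_that("segments partition the trace with no double counting", {
  set.seed(3)
  cfg <- small_cohort_config(seed = 3, n_subjects = 1, n_trials = 3)
  tr <- simulate_cohort(cfg)$traces[[1]]
  seg <- classify_motion(tr)
  expect_equal(seg$start_frame[1], 1)
  expect_equal(seg$end_frame[nrow(seg)], nrow(tr))
  expect_equal(seg$start_frame[-1], seg$end_frame[-nrow(seg)])
})

test_that("pause detection: exclusion, outcome, duration rules", {
  fps <- 30; dt <- 1 / fps
  # pause inside the Start box (x = -5) is excluded
  x <- c(seq(-12, -5, by = 0.7), rep(-5, 6), seq(-4.3, 10, by = 0.7))
  tr <- tracking_trace(seq_along(x) * dt, x)
  p <- detect_pauses(classify_motion(tr), tr)
  expect_equal(nrow(p), 0)
  # pause at x = 50 followed by toward_start movement -> avoid
  x2 <- c(seq(40, 50, by = 0.7), rep(50, 8), seq(49.3, 35, by = -0.7))
  tr2 <- tracking_trace(seq_along(x2) * dt, x2)
  p2 <- detect_pauses(classify_motion(tr2), tr2)
  expect_equal(nrow(p2), 1)
  expect_equal(p2$outcome, "avoid")
  expect_equal(p2$zone, "mid")
  expect_equal(p2$x_cm, 50, tolerance = 0.01)
  # trailing pause with no subsequent movement is dropped
  x3 <- c(seq(40, 50, by = 0.7), rep(50, 10))
  tr3 <- tracking_trace(seq_along(x3) * dt, x3)
  expect_equal(nrow(detect_pauses(classify_motion(tr3), tr3)), 0)
})

test_that("every detected pause satisfies the stated rules", {
  cfg <- small_cohort_config(seed = 11)
  coh <- simulate_cohort(cfg)
  for (sid in names(coh$traces)) {
    tr <- coh$traces[[sid]]
    seg <- classify_motion(tr)
    p <- detect_pauses(seg, tr)
    expect_true(all(p$rt_s >= 0.090 - 1e-9))
    expect_true(all(p$x_cm >= 0 & p$x_cm <= 88))
    # the resolving movement covers >= 1.5 cm uninterrupted
    mv <- seg[seg$state != "paused", ]
    expect_true(all(abs(mv$displacement) >= 1.5 - 1e-9))
  }
})

test_that("pause detection is idempotent and time-shift invariant", {
  cfg <- small_cohort_config(seed = 5, n_subjects = 1, n_trials = 4)
  tr <- simulate_cohort(cfg)$traces[[1]]
  p1 <- detect_pauses(classify_motion(tr), tr)
  p2 <- detect_pauses(classify_motion(tr), tr)
  expect_identical(p1, p2)
  sh <- tr; sh$time_s <- sh$time_s + 123.4
  p3 <- detect_pauses(classify_motion(sh), sh)
  expect_equal(p3$onset_s, p1$onset_s + 123.4)
  expect_equal(p3$rt_s, p1$rt_s)
  expect_equal(p3$outcome, p1$outcome)
})

test_that("detection recovers generated pauses at low noise", {
  coh <- simulate_cohort(cohort_config(n_subjects = 2, n_trials = 10,
                                       seed = 19))
  det <- do.call(rbind, lapply(names(coh$traces), function(s) {
    tr <- coh$traces[[s]]
    detect_pauses(classify_motion(tr), tr)
  }))
  m <- match_pauses(det, coh$truth$pauses)
  expect_gte(m$recall, 0.95)
  expect_gte(m$outcome_agreement, 0.95)
})

test_that("zone clustering recovers separable location groups", {
  # bins identical except location, three separated groups -> the two
  # gaps are the boundaries
  set.seed(2)
  # bin centers; each group stays inside one 5 cm bin, with equal
  # counts, durations and outcome mix, so only location separates them
  mk <- function(xs) do.call(rbind, lapply(xs, function(x)
    data.frame(subject = "s1", session = "a",
               onset_s = runif(8), offset_s = 1, rt_s = 0.5,
               x_cm = x + runif(8, -0.5, 0.5), zone = "mid",
               outcome = rep(c("approach", "avoid"), 4))))
  pauses <- mk(c(2.5, 7.5, 42.5, 47.5, 52.5, 82.5, 87))
  z <- cluster_zones(pauses, k = 3)
  expect_true(z$contiguous)
  expect_equal(length(z$boundaries), 2)
  expect_gt(z$boundaries[1], 10); expect_lt(z$boundaries[1], 40)
  expect_gt(z$boundaries[2], 50); expect_lt(z$boundaries[2], 80)
  expect_true(all(z$silhouette >= -1 & z$silhouette <= 1))
  # degenerate k = 1
  z1 <- cluster_zones(pauses, k = 1)
  expect_equal(z1$k, 1)
  expect_true(is.na(z1$mean_sil))
  expect_error(cluster_zones(pauses[pauses$x_cm < 12, ], k = 10))
})

test_that("log-normal RT summary recovers known parameters", {
  set.seed(8)
  d <- data.frame(subject = "s1", session = "a", onset_s = 0,
                  offset_s = 1, rt_s = rlnorm(5000, -1, 0.8),
                  x_cm = runif(5000, 0, 88), zone = "mid",
                  outcome = "approach")
  s <- summarize_rts(d)
  expect_equal(s$mu, -1, tolerance = 0.05)
  expect_equal(s$sigma, 0.8, tolerance = 0.05)
  expect_gt(s$r2_lognormal, 0.9)
  # all-equal durations: sigma 0, histogram fit flagged
  d2 <- d[1:50, ]; d2$rt_s <- 0.4
  s2 <- summarize_rts(d2)
  expect_equal(s2$sigma, 0)
  expect_true(is.na(s2$r2_lognormal))
  expect_match(s2$flag, "zero variance")
  # fewer than 20 events: fit fields absent
  expect_true(is.na(summarize_rts(d[1:5, ])$mu))
})

test_that("CV linearity is perfect on proportional mean-SD data", {
  # construct per-bin RT samples with sd proportional to mean
  set.seed(9)
  rows <- list()
  for (b in 1:8) {
    m <- 0.2 * b
    z <- scale(rnorm(30))  # exact mean 0, sd 1
    rows[[b]] <- data.frame(subject = "s1", session = "a", onset_s = 0,
                            offset_s = 1, rt_s = m + 0.3 * m * z,
                            x_cm = b * 5 - 2.5, zone = "mid",
                            outcome = "approach")
  }
  s <- summarize_rts(do.call(rbind, rows))
  expect_equal(s$cv_r2, 1, tolerance = 1e-9)
  expect_equal(s$cv_slope, 0.3, tolerance = 1e-6)
})

test_that("session metrics: dwell, velocity, latency", {
  fps <- 30; dt <- 1 / fps
  # stationary in the Start box
  tr <- tracking_trace((1:60) * dt, rep(-10, 60))
  m <- summarize_session(tr)
  expect_equal(m$time_track, 0)
  expect_equal(m$time_goal_box, 0)
  expect_gt(m$time_start_box, 0)
  expect_true(all(abs(m$velocity) < 1e-9))
  expect_true(is.na(m$latency_to_goal))
  # constant-speed traversal at 20 cm/s
  x <- seq(-5, 95, by = 20 * dt)
  tr2 <- tracking_trace(seq_along(x) * dt, x)
  m2 <- summarize_session(tr2)
  inner <- m2$velocity[2:(length(x) - 1)]
  expect_equal(inner, rep(20, length(inner)), tolerance = 1e-9)
  expect_equal(m2$dist_from_goal, 88 - x)
  # latency equals the generative traversal time +- 1 frame
  cross <- which(x > 88)[1]
  expect_equal(m2$latency_to_goal, (cross - 1) * dt, tolerance = dt)
})
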