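# Photometry: dF/F correctness against constructions with known
# artifacts and injected signals, kernel extraction, bootstrap bands
# and their operating characteristics, spatial maps and pause means.

test_that("dF/F is zero when channels are exactly proportional", {
  t <- seq(0, 100, by = 0.05)
  iso <- 1 + 0.1 * sin(t / 7)
  rec <- list(time_s = t, ca_signal = 2 * iso, iso_signal = iso)
  d <- compute_dff(rec)
  expect_lt(max(abs(d$dff)), 1e-12)
  expect_equal(d$slope, 2)
  expect_equal(d$intercept, 0, tolerance = 1e-10)
  expect_error(compute_dff(list(time_s = t, ca_signal = iso,
                                iso_signal = rep(1, length(t)))),
               "constant")
})

test_that("dF/F removes a known multiplicative artifact", {
  set.seed(12)
  n <- 1e5
  t <- seq_len(n) / 30
  artifact <- 1 + 0.15 * sin(t / 11) + 0.05 * sin(t / 3.7)
  iso <- artifact + rnorm(n, 0, 0.005)
  ca <- 1.5 * artifact + rnorm(n, 0, 0.005)
  d <- compute_dff(list(time_s = t, ca_signal = ca, iso_signal = iso))
  expect_lt(abs(cor(d$dff, artifact)), 0.05)
})

test_that("an injected multiplicative transient is recovered", {
  set.seed(14)
  n <- 2e4
  t <- seq_len(n) / 30
  artifact <- 1 + 0.1 * sin(t / 9)
  sig <- numeric(n)
  on <- t >= 300 & t < 301
  sig[on] <- 0.05
  iso <- artifact + rnorm(n, 0, 0.002)
  ca <- 1.5 * artifact * (1 + sig) + rnorm(n, 0, 0.002)
  d <- compute_dff(list(time_s = t, ca_signal = ca, iso_signal = iso))
  peak <- mean(d$dff[on])
  expect_lt(abs(peak - 0.05) / 0.05, 0.1)
  # invariance to common rescaling of both channels
  d2 <- compute_dff(list(time_s = t, ca_signal = 7.3 * ca,
                         iso_signal = 7.3 * iso))
  expect_equal(d2$dff, d$dff, tolerance = 1e-10)
})

test_that("kernel extraction baselines and aligns correctly", {
  t <- seq(0, 60, by = 1 / 30)
  # constant dff -> all baselined waveforms identically zero
  d <- structure(list(time_s = t, dff = rep(0.37, length(t))),
                 class = "dff_trace")
  k <- extract_kernels(d, events = c(10, 20, 30))
  expect_equal(k$n_events, 3)
  expect_lt(max(abs(k$waveforms)), 1e-12)
  # a step of +1 at the event time: 0 before, +1 after
  d2 <- structure(list(time_s = t, dff = as.numeric(t >= 30)),
                  class = "dff_trace")
  k2 <- extract_kernels(d2, events = 30)
  expect_equal(as.numeric(k2$waveforms[1, k2$time < -0.1]),
               rep(0, sum(k2$time < -0.1)), tolerance = 1e-9)
  expect_equal(as.numeric(k2$waveforms[1, k2$time > 0.1]),
               rep(1, sum(k2$time > 0.1)), tolerance = 1e-9)
  # events too close to the edges are dropped
  k3 <- extract_kernels(d, events = c(2, 58, 30))
  expect_equal(k3$n_events, 1)
  expect_equal(k3$n_dropped, 2)
})

test_that("noisy injected kernels are recovered by the mean waveform", {
  set.seed(15)
  t <- seq(0, 600, by = 1 / 30)
  events <- seq(20, 580, by = 20)
  kern_shape <- function(tau) ifelse(tau >= 0 & tau < 3,
                                     (1 - exp(-tau / 0.2)) *
                                       exp(-tau / 0.8), 0)
  sig <- Reduce(`+`, lapply(events, function(e) kern_shape(t - e)))
  amp <- 0.05
  noise_sd <- amp / 5 # SNR 5
  d <- structure(list(time_s = t,
                      dff = amp * sig + rnorm(length(t), 0, noise_sd)),
                 class = "dff_trace")
  k <- extract_kernels(d, events)
  inj <- amp * kern_shape(k$time)
  expect_gt(cor(k$mean, inj), 0.9)
  expect_lt(abs(max(k$mean) - amp * max(kern_shape(seq(0, 3, 0.01)))) /
              amp, 0.15)
})

test_that("bootstrap band: degenerate and arithmetic cases", {
  time <- seq(-5, 5, by = 0.05)
  # identical subject waveforms: zero-width band
  wf <- matrix(rep(0.3, 4 * length(time)), 4, byrow = TRUE)
  b <- bootstrap_ci(wf, time, n_boot = 200, seed = 1)
  expect_equal(b$ci_lo, rep(0.3, length(time)))
  expect_equal(b$ci_hi, rep(0.3, length(time)))
  expect_equal(nrow(b$epochs), 1)
  expect_equal(b$epochs$sign, "positive")
  # identically zero: band at zero, no epochs
  b0 <- bootstrap_ci(matrix(0, 4, length(time)), time, n_boot = 200,
                     seed = 1)
  expect_equal(nrow(b0$epochs), 0)
  # expansion factor arithmetic
  expect_equal(bootstrap_ci(matrix(rnorm(5 * 11), 5, 11), seq_len(11),
                            n_boot = 50, seed = 2)$expansion,
               sqrt(5 / 4))
  expect_equal(bootstrap_ci(matrix(rnorm(2 * 11), 2, 11), seq_len(11),
                            n_boot = 50, seed = 2)$expansion, sqrt(2))
  expect_error(bootstrap_ci(matrix(0, 1, 11), seq_len(11)), "2 subjects")
})

test_that("bootstrap band width shrinks like 1/sqrt(n)", {
  set.seed(16)
  time <- seq(-5, 5, by = 0.05)
  width <- function(n) {
    wf <- matrix(rnorm(n * length(time)), n)
    b <- bootstrap_ci(wf, time, n_boot = 400, seed = 3)
    mean(b$ci_hi - b$ci_lo)
  }
  w4 <- width(4); w16 <- width(16); w64 <- width(64)
  expect_lt(abs(w4 / w16 - 2), 0.3)
  expect_lt(abs(w16 / w64 - 2), 0.3)
})

test_that("significant-epoch detection: hits and false-positive rate", {
  time <- seq(-5, 5, by = 0.05)
  sigma <- 0.01
  n_sub <- 8
  hit <- 0; fp <- 0
  n_rep <- 30
  for (r in seq_len(n_rep)) {
    set.seed(1000 + r)
    null_wf <- matrix(rnorm(n_sub * length(time), 0, sigma), n_sub)
    bn <- bootstrap_ci(null_wf, time, n_boot = 400, seed = r)
    if (nrow(bn$epochs) > 0) fp <- fp + 1
    inj <- null_wf
    on <- time >= 0 & time < 1
    inj[, on] <- inj[, on] + 10 * sigma
    bi <- bootstrap_ci(inj, time, n_boot = 400, seed = r)
    covers <- any(bi$epochs$start_s < 0.9 & bi$epochs$end_s > 0.1 &
                    bi$epochs$sign == "positive")
    if (covers) hit <- hit + 1
  }
  expect_equal(hit, n_rep)
  expect_lte(fp / n_rep, 0.2)
})

test_that("epoch boundaries are stable under reseeding", {
  time <- seq(-5, 5, by = 0.05)
  set.seed(17)
  wf <- matrix(rnorm(8 * length(time), 0, 0.01), 8)
  on <- time >= 0 & time < 1
  wf[, on] <- wf[, on] + 0.1
  b1 <- bootstrap_ci(wf, time, n_boot = 1000, seed = 1)
  b2 <- bootstrap_ci(wf, time, n_boot = 1000, seed = 999)
  expect_equal(nrow(b1$epochs), nrow(b2$epochs))
  expect_lt(max(abs(b1$epochs$start_s - b2$epochs$start_s)), 0.1)
  expect_lt(max(abs(b1$epochs$end_s - b2$epochs$end_s)), 0.1)
})

test_that("spatial map: trivial, ramp and goal-locked constructions", {
  geom <- track_geometry()
  t <- seq(0, 500, by = 1 / 30)
  x <- 88 * (0.5 + 0.5 * sin(t / 13))
  d0 <- structure(list(time_s = t, dff = numeric(length(t)), x_cm = x),
                  class = "dff_trace")
  m0 <- spatial_dff(d0, geom)
  expect_true(all(abs(m0$bin_mean) < 1e-12, na.rm = TRUE))
  # generator ramp mode: bin means increase toward the goal
  cfg <- cohort_config(n_subjects = 1, n_trials = 6,
                       photometry_mode = "spatial_ramp", noise_sd = 0.002,
                       seed = 23)
  coh <- simulate_cohort(cfg)
  d <- compute_dff(coh$photometry[[1]])
  m <- spatial_dff(d, geom)
  ok <- !is.na(m$bin_mean)
  expect_gt(cor(m$bin_mid[ok], m$bin_mean[ok], method = "spearman"), 0.9)
  # goal-locked mode: goal-zone mean exceeds mid-zone mean
  cfg2 <- cohort_config(n_subjects = 1, n_trials = 6, seed = 24)
  coh2 <- simulate_cohort(cfg2)
  d2 <- compute_dff(coh2$photometry[[1]])
  m2 <- spatial_dff(d2, geom)
  expect_gt(m2$zone_mean[["goal"]], m2$zone_mean[["mid"]])
})

test_that("pause means: constant dff and goal-locked contrasts", {
  cfg <- small_cohort_config(seed = 25)
  coh <- simulate_cohort(cfg)
  pauses <- do.call(rbind, lapply(names(coh$traces), function(s) {
    tr <- coh$traces[[s]]
    detect_pauses(classify_motion(tr), tr)
  }))
  tr1 <- coh$traces[[1]]
  dconst <- structure(list(time_s = tr1$time_s,
                           dff = rep(0.02, nrow(tr1))),
                      class = "dff_trace")
  pd <- pause_dff(dconst, pauses[pauses$subject == "s01", ])
  expect_equal(pd$per_pause$mean_dff,
               rep(0.02, nrow(pd$per_pause)))
  # goal-locked: goal-zone pause dF/F above start-zone, per subject
  for (sid in names(coh$traces)) {
    d <- compute_dff(coh$photometry[[sid]])
    agg <- pause_dff(d, pauses[pauses$subject == sid, ])$per_zone
    g <- agg$mean_dff[agg$zone == "goal"]
    st <- agg$mean_dff[agg$zone == "start"]
    if (length(g) && length(st)) expect_gt(g, st)
  }
  # pauses outside the recording span are dropped and counted
  short <- structure(list(time_s = tr1$time_s[1:100],
                          dff = rep(0, 100)), class = "dff_trace")
  pd2 <- pause_dff(short, pauses[pauses$subject == "s01", ])
  expect_gt(pd2$n_dropped, 0)
})
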