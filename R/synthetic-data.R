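# Ground-truth-labeled synthetic cohorts: linear-track trajectories
# with LBA-resolved pauses, and two-channel photometry sharing a
# multiplicative artifact with either goal-locked transients or
# spatially ramping signal. The generator states the world the
# downstream stages assume; every generated pause carries its
# generative (choice, RT) so detection and model fits can be scored.

#' Default per-zone LBA parameters for the synthetic cohort
#'
#' Encodes the qualitative decision structure the pipeline is built to
#' recover: approach drift dominates in the start and mid zones, the
#' drift advantage reverses at the goal (danger salience exceeds reward
#' salience there), and goal-zone caution is 1.5x mid-zone caution
#' (k = 0.875 vs 0.5 with A = 0.5, so caution 1.125 vs 0.75).
#'
#' @return named list of [lba_params] for zones "start", "mid", "goal".
#' @export
default_zone_params <- function() {
  list(start = lba_params(v = c(3.0, 1.6), A = 0.5, k = 0.5, t0 = 0.15),
       mid = lba_params(v = c(3.5, 1.2), A = 0.5, k = 0.5, t0 = 0.15),
       goal = lba_params(v = c(2.0, 2.6), A = 0.5, k = 0.875, t0 = 0.15))
}

#' Default spatial pause hazard (pauses per cm traversed)
#'
#' Bimodal: pausing peaks near the start of the track and again just
#' before the goal, with a low floor in between.
#'
#' @return function of track position x (cm) -> hazard (pauses/cm).
#' @export
default_pause_hazard <- function() {
  function(x) {
    0.02 + 0.25 * exp(-(x - 3)^2 / (2 * 5^2)) +
      0.35 * exp(-(x - 86)^2 / (2 * 3^2))
  }
}

#' Synthetic cohort configuration
#'
#' @param n_subjects number of subjects (default 8).
#' @param n_trials trials per subject session (default 20).
#' @param frame_rate tracking frame rate, Hz (default 30).
#' @param geometry a [track_geometry].
#' @param zone_params named list of [lba_params] per zone label
#'   ("start", "mid", "goal").
#' @param pause_hazard function x -> pauses per cm traversed (>= 0).
#' @param run_speed_mean,run_speed_sd running speed draw per run, cm/s.
#' @param pos_noise_sd per-frame tracking jitter SD, cm (default 0.03,
#'   well below the 0.2 cm stillness tolerance).
#' @param subject_sd log-scale SD of per-subject jitter applied to
#'   drift rates and thresholds (default 0.08).
#' @param photometry_mode "goal_locked" (transients at goal-zone pause
#'   onsets, PVT-like) or "spatial_ramp" (activity ramping with
#'   proximity to the goal, vSub-like).
#' @param transient_amplitude peak fractional dF/F of injected signal.
#' @param noise_sd additive channel noise, as a fraction of baseline.
#' @param artifact_gain amplitude of the shared multiplicative artifact.
#' @param trial_timeout trial time limit, s (default 120).
#' @param seed integer seed.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 8, n_trials = 20, frame_rate = 30,
                          geometry = track_geometry(),
                          zone_params = default_zone_params(),
                          pause_hazard = default_pause_hazard(),
                          run_speed_mean = 20, run_speed_sd = 3,
                          pos_noise_sd = 0.03, subject_sd = 0.08,
                          photometry_mode = c("goal_locked",
                                              "spatial_ramp"),
                          transient_amplitude = 0.05, noise_sd = 0.005,
                          artifact_gain = 0.1, trial_timeout = 120,
                          seed = 1) {
  photometry_mode <- match.arg(photometry_mode)
  stopifnot(n_subjects >= 1, n_trials >= 1, frame_rate > 0,
            is.function(pause_hazard), run_speed_mean > 0,
            all(c("start", "mid", "goal") %in% names(zone_params)))
  for (zp in zone_params) stopifnot(inherits(zp, "lba_params"))
  xs <- seq(0, geometry$track_len, by = 1)
  if (any(pause_hazard(xs) < 0)) stop("pause hazard must be >= 0")
  structure(list(n_subjects = n_subjects, n_trials = n_trials,
                 frame_rate = frame_rate, geometry = geometry,
                 zone_params = zone_params, pause_hazard = pause_hazard,
                 run_speed_mean = run_speed_mean,
                 run_speed_sd = run_speed_sd,
                 pos_noise_sd = pos_noise_sd, subject_sd = subject_sd,
                 photometry_mode = photometry_mode,
                 transient_amplitude = transient_amplitude,
                 noise_sd = noise_sd, artifact_gain = artifact_gain,
                 trial_timeout = trial_timeout, seed = seed),
            class = "cohort_config")
}

#' Simulate one trial trajectory with LBA-resolved pauses
#'
#' The animal leaves the Start box, runs toward the goal at a per-run
#' speed, and initiates pauses on the track according to the spatial
#' hazard (probability `hazard(x) * |dx|` per frame step). Each pause
#' draws a (choice, RT) pair from the local zone's LBA race; the pause
#' lasts the drawn RT, then approach resumes motion toward the goal and
#' avoid reverses toward the start, producing bistable start-goal
#' oscillations. Reaching the Goal box (plus a consumption dwell) ends
#' the trial, as does the timeout. A short refractory distance (2 cm)
#' after each pause keeps consecutive decisions separated by at least
#' one detectable movement.
#'
#' @param subject_params named list of [lba_params] per zone.
#' @param config a [cohort_config].
#' @param t_start session time of the trial's first frame, s.
#' @param subject_id,session_id identifiers for the trace.
#' @return list with `trace` (a [tracking_trace]) and `truth`
#'   (data.frame of generative pauses: onset/offset times and frames,
#'   location, zone, choice, outcome, exact RT).
#' @export
simulate_trial_trajectory <- function(subject_params, config,
                                      t_start = 0, subject_id = "s1",
                                      session_id = "sess1") {
  geom <- config$geometry
  dt <- 1 / config$frame_rate
  zb <- geom$zone_boundaries
  for (z in c("start", "mid", "goal")) {
    if (is.null(subject_params[[z]]))
      stop("no LBA parameters for zone '", z, "'")
  }
  draw_speed <- function() max(2, stats::rnorm(1, config$run_speed_mean,
                                               config$run_speed_sd))
  max_frames <- ceiling(config$trial_timeout / dt)
  x <- numeric(max_frames + 1)
  x[1] <- -geom$start_box_len / 2
  dir <- 1; speed <- draw_speed()
  truth <- list()
  i <- 1
  since_pause <- Inf # cm traversed since last pause (refractory)
  goal_dwell <- ceiling(1.5 / dt)
  in_goal <- 0L
  while (i <= max_frames) {
    xi <- x[i]
    on_track <- xi >= 0 && xi <= geom$track_len
    step <- dir * speed * dt
    if (on_track && since_pause > 2 &&
        stats::runif(1) < config$pause_hazard(xi) * abs(step)) {
      zone <- zone_of(xi, geom)
      race <- sample_race(subject_params[[zone]], 1)
      n_still <- max(3L, as.integer(round(race$rt / dt)))
      n_still <- min(n_still, max_frames - i)
      if (n_still >= 3L) {
        hold <- xi + stats::rnorm(n_still, 0, config$pos_noise_sd)
        x[(i + 1):(i + n_still)] <- hold
        truth[[length(truth) + 1]] <- data.frame(
          subject = subject_id, session = session_id,
          onset_s = t_start + (i - 1) * dt,
          offset_s = t_start + (i - 1 + n_still) * dt,
          onset_frame = i, offset_frame = i + n_still,
          x_cm = xi, zone = zone,
          choice = race$choice,
          outcome = if (race$choice == 1) "approach" else "avoid",
          rt_s = race$rt)
        i <- i + n_still
        dir <- if (race$choice == 1) 1 else -1
        speed <- draw_speed()
        since_pause <- 0
        next
      }
    }
    nx <- xi + step + stats::rnorm(1, 0, config$pos_noise_sd)
    nx <- min(max(nx, -geom$start_box_len + 1),
              geom$track_len + geom$goal_box_len - 1)
    x[i + 1] <- nx
    since_pause <- since_pause + abs(step)
    i <- i + 1
    if (nx > geom$track_len) {
      in_goal <- in_goal + 1L
      if (in_goal >= goal_dwell) break # reward consumed, trial over
    } else if (nx < -2 && dir < 0) {
      # back in the Start box: brief dwell, then head out again
      dwell <- min(as.integer(round(stats::runif(1, 0.5, 1.5) / dt)),
                   max_frames - i)
      if (dwell > 0) {
        x[(i + 1):(i + dwell)] <- nx +
          stats::rnorm(dwell, 0, config$pos_noise_sd)
        i <- i + dwell
      }
      dir <- 1; speed <- draw_speed()
    }
  }
  n <- min(i, max_frames + 1)
  tm <- t_start + (seq_len(n) - 1) * dt
  trace <- tracking_trace(tm, x[seq_len(n)],
                          y = stats::rnorm(n, 0, 0.3),
                          subject_id = subject_id,
                          session_id = session_id)
  truth <- if (length(truth)) do.call(rbind, truth) else NULL
  list(trace = trace, truth = truth)
}

#' Simulate a two-channel photometry recording for a trace
#'
#' Both channels share a multiplicative artifact (slow sinusoidal
#' drift plus a motion-coupled component, scaled by `artifact_gain`).
#' The isosbestic channel is `baseline * artifact`; the calcium channel
#' is `baseline * artifact * (1 + signal)`, where the signal is either
#' a transient kernel at each goal-zone pause onset (`goal_locked`) or
#' an amplitude ramp with proximity to the goal (`spatial_ramp`).
#' Broadband photoreceiver noise of SD `noise_sd * baseline` is added
#' to each channel after passing through the acquisition chain's 3 Hz
#' low-pass (a two-pass exponential smoother), which band-limits it
#' the way the recording hardware does.
#'
#' @param trace a [tracking_trace] (photometry is sampled on its
#'   timestamps).
#' @param truth generative pause table from the same simulation (used
#'   for goal-locked transient placement); may be `NULL`.
#' @param config a [cohort_config].
#' @param amplitude transient amplitude for this subject (defaults to
#'   `config$transient_amplitude`).
#' @return object of class `photometry_recording`: list with `time_s`,
#'   `ca_signal`, `iso_signal`, `x_cm`, `events` (goal-pause onsets),
#'   and `truth` (generative `signal` and `artifact` traces,
#'   transient times and amplitude).
#' @export
simulate_photometry <- function(trace, truth, config,
                                amplitude = NULL) {
  if (is.null(amplitude)) amplitude <- config$transient_amplitude
  tm <- trace$time_s; x <- trace$x_cm
  n <- length(tm)
  g <- config$artifact_gain
  ph <- stats::runif(2, 0, 2 * pi)
  drift <- 0.6 * sin(2 * pi * tm / 97 + ph[1]) +
    0.4 * sin(2 * pi * tm / 41 + ph[2])
  vel <- c(0, abs(diff(x))) * config$frame_rate
  vmot <- if (max(vel) > 0) vel / max(vel) - mean(vel / max(vel)) else 0
  artifact <- pmax(1 + g * drift + 0.3 * g * vmot, 0.2)
  signal <- numeric(n)
  trans_times <- numeric(0)
  if (config$photometry_mode == "goal_locked") {
    if (!is.null(truth)) {
      trans_times <- truth$onset_s[truth$zone == "goal"]
      for (t0 in trans_times) {
        tau <- tm - t0
        w <- tau >= 0 & tau < 5
        kern <- (1 - exp(-tau[w] / 0.1)) * exp(-tau[w] / 0.5)
        signal[w] <- signal[w] + amplitude * kern / max(kern, 1e-12)
      }
    }
  } else {
    signal <- amplitude * pmax(x, 0) / config$geometry$track_len
  }
  # acquisition low-pass (3 Hz) applied to the broadband channel noise
  lp3 <- function(e) {
    alpha <- (1 / config$frame_rate) /
      (1 / config$frame_rate + 1 / (2 * pi * 3))
    for (pass in 1:2) e <- stats::filter(e * alpha, 1 - alpha,
                                         method = "recursive")
    as.numeric(e)
  }
  iso_base <- 1; ca_base <- 1.5
  iso <- iso_base * artifact +
    lp3(stats::rnorm(n, 0, config$noise_sd * iso_base))
  ca <- ca_base * artifact * (1 + signal) +
    lp3(stats::rnorm(n, 0, config$noise_sd * ca_base))
  structure(list(time_s = tm, ca_signal = ca, iso_signal = iso,
                 x_cm = x, events = trans_times,
                 truth = list(signal = signal, artifact = artifact,
                              transient_times = trans_times,
                              amplitude = amplitude)),
            class = "photometry_recording")
}

#' Simulate a full cohort with ground truth
#'
#' Per-subject streams are seeded independently from `config$seed`, so
#' the cohort is reproducible as a whole and per subject. Each
#' subject's zone parameters receive a small log-normal jitter
#' (`subject_sd`) around the cohort defaults; the jittered truth is
#' recorded.
#'
#' @param config a [cohort_config].
#' @return object of class `synthetic_cohort`: list with `traces`
#'   (per-subject [tracking_trace]), `photometry` (per-subject
#'   [photometry_recording]), `truth` (list: `pauses` data.frame across
#'   subjects, `subject_params` nested list, `config`).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  traces <- list(); photo <- list(); pauses <- list(); spars <- list()
  for (s in seq_len(config$n_subjects)) {
    set.seed(config$seed + 7919L * s)
    sid <- sprintf("s%02d", s)
    jit <- function(p) {
      lba_params(v = p$v * exp(stats::rnorm(length(p$v), 0,
                                            config$subject_sd)),
                 A = p$A,
                 k = p$k * exp(stats::rnorm(1, 0, config$subject_sd)),
                 t0 = p$t0)
    }
    sp <- lapply(config$zone_params, jit)
    spars[[sid]] <- sp
    t_cursor <- 0
    sub_traces <- list(); sub_truth <- list()
    for (tr in seq_len(config$n_trials)) {
      sim <- simulate_trial_trajectory(sp, config, t_start = t_cursor,
                                       subject_id = sid,
                                       session_id = "sess1")
      sub_traces[[tr]] <- sim$trace
      if (!is.null(sim$truth)) {
        sim$truth$trial <- tr
        sub_truth[[length(sub_truth) + 1]] <- sim$truth
      }
      # 2 s inter-trial interval back in the Start box
      t_cursor <- max(sim$trace$time_s) + 2
    }
    full <- do.call(rbind, lapply(sub_traces, as.data.frame))
    trace <- tracking_trace(full$time_s, full$x_cm, full$y_cm,
                            subject_id = sid, session_id = "sess1")
    truth <- if (length(sub_truth)) do.call(rbind, sub_truth) else NULL
    amp <- config$transient_amplitude *
      exp(stats::rnorm(1, 0, config$subject_sd))
    traces[[sid]] <- trace
    photo[[sid]] <- simulate_photometry(trace, truth, config,
                                        amplitude = amp)
    pauses[[sid]] <- truth
  }
  structure(list(
    traces = traces, photometry = photo,
    truth = list(pauses = do.call(rbind, pauses),
                 subject_params = spars, config = config)),
    class = "synthetic_cohort")
}
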