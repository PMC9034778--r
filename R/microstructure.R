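# Behavioral microstructure on the linear track: gap interpolation,
# motion-state classification, pause (approach-avoid decision)
# detection, spatial zone clustering and RT summaries.
#
# Coordinate convention: 1-D track-proper coordinate, 0 at the Start
# box door, increasing toward the goal. The Start box occupies negative
# x, the Goal box x > track_len. Only pauses with 0 <= x <= track_len
# ("on the track") enter analysis and modeling.

#' Linear-track geometry
#'
#' Defaults describe a 120 cm apparatus: 22 cm Start box, 88 cm track
#' proper, 10 cm Goal box; analysis bins of 5 cm; default decision-zone
#' boundaries at 15 cm (start/mid) and 83 cm (mid/goal, i.e. 5 cm from
#' the goal).
#'
#' @param start_box_len,track_len,goal_box_len lengths in cm.
#' @param bin_width spatial bin width, cm.
#' @param zone_boundaries ordered boundaries on track proper, cm.
#' @return object of class `track_geometry`.
#' @export
track_geometry <- function(start_box_len = 22, track_len = 88,
                           goal_box_len = 10, bin_width = 5,
                           zone_boundaries = c(15, 83)) {
  stopifnot(start_box_len > 0, track_len > 0, goal_box_len > 0,
            bin_width > 0,
            all(diff(zone_boundaries) > 0),
            all(zone_boundaries > 0), all(zone_boundaries < track_len))
  structure(list(start_box_len = start_box_len, track_len = track_len,
                 goal_box_len = goal_box_len, bin_width = bin_width,
                 zone_boundaries = zone_boundaries),
            class = "track_geometry")
}

#' Zone label of a track position
#'
#' @param x positions, cm (track-proper coordinate).
#' @param geometry a [track_geometry].
#' @return character vector: "start", "mid", "goal" for on-track
#'   positions, "start_box"/"goal_box" outside.
#' @export
zone_of <- function(x, geometry = track_geometry()) {
  zb <- geometry$zone_boundaries
  out <- rep("mid", length(x))
  out[x < zb[1]] <- "start"
  out[x >= zb[2]] <- "goal"
  out[x < 0] <- "start_box"
  out[x > geometry$track_len] <- "goal_box"
  out
}

#' Construct a tracking trace
#'
#' @param timestamps seconds, strictly increasing.
#' @param x,y positions, cm (x in the track-proper coordinate).
#' @param valid logical per frame; invalid frames carry unusable
#'   positions and are repaired by [interpolate_gaps].
#' @param subject_id,session_id identifiers.
#' @return object of class `tracking_trace` (a data.frame).
#' @export
tracking_trace <- function(timestamps, x, y = NULL, valid = NULL,
                           subject_id = "s1", session_id = "sess1") {
  n <- length(timestamps)
  stopifnot(length(x) == n, n >= 2)
  ok <- diff(timestamps) > 0
  if (!all(ok)) stop("timestamps must be strictly increasing")
  if (is.null(y)) y <- rep(0, n)
  if (is.null(valid)) valid <- rep(TRUE, n)
  df <- data.frame(frame = seq_len(n), time_s = timestamps,
                   x_cm = x, y_cm = y, valid = as.logical(valid))
  attr(df, "subject_id") <- subject_id
  attr(df, "session_id") <- session_id
  class(df) <- c("tracking_trace", "data.frame")
  df
}

#' Repair tracking dropouts by linear interpolation
#'
#' Invalid frames between valid neighbors are filled by linear
#' interpolation in time; leading/trailing invalid frames take the
#' nearest valid value. All frames are marked valid on return.
#'
#' @param trace a [tracking_trace].
#' @return the trace with `x_cm`, `y_cm` filled and `valid` all-TRUE.
#' @export
interpolate_gaps <- function(trace) {
  v <- trace$valid
  if (sum(v) < 2) stop("unusable trace: fewer than 2 valid frames")
  if (all(v)) return(trace)
  for (col in c("x_cm", "y_cm")) {
    trace[[col]] <- stats::approx(trace$time_s[v], trace[[col]][v],
                                  xout = trace$time_s, method = "linear",
                                  rule = 2)$y
  }
  trace$valid <- TRUE
  trace
}

#' Classify frames into motion states
#'
#' Each inter-frame step is labeled still (|dx| below the stillness
#' tolerance), toward_goal (dx > 0) or toward_start (dx < 0); runs of
#' identical labels form segments. Movement runs whose cumulative
#' displacement is below `move_threshold` (1.5 cm) are tracking jitter
#' and are relabeled as paused, so every surviving toward_* segment
#' carries an uninterrupted displacement of at least 1.5 cm. A paused
#' segment therefore means: no movement (each step < `still_tol`),
#' and it qualifies as a decision pause only if it lasts >= `min_pause`
#' (90 ms) and is followed by a toward_* segment.
#'
#' @param trace gap-filled [tracking_trace].
#' @param geometry a [track_geometry].
#' @param still_tol per-frame displacement below which the animal
#'   counts as not moving, cm (default 0.2).
#' @param move_threshold minimum uninterrupted displacement of a
#'   movement segment, cm (default 1.5).
#' @param min_pause minimum stillness duration of a decision pause, s
#'   (default 0.090).
#' @return data.frame of motion segments: `start_frame`, `end_frame`,
#'   `start_time`, `end_time`, `state`, `displacement`, `qualifies`
#'   (for paused segments: long enough and followed by movement).
#' @export
classify_motion <- function(trace, geometry = track_geometry(),
                            still_tol = 0.2, move_threshold = 1.5,
                            min_pause = 0.090) {
  stopifnot(all(trace$valid))
  x <- trace$x_cm; tm <- trace$time_s
  dx <- diff(x)
  lab <- ifelse(abs(dx) < still_tol, 0L, ifelse(dx > 0, 1L, -1L))
  # runs over steps
  r <- rle(lab)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  disp <- vapply(seq_along(starts),
                 function(i) x[ends[i] + 1] - x[starts[i]], numeric(1))
  state <- r$values
  # sub-threshold movement runs are jitter -> relabel still, then merge
  state[state != 0L & abs(disp) < move_threshold] <- 0L
  merged <- list(); i <- 1
  while (i <= length(state)) {
    j <- i
    while (j < length(state) && state[j + 1] == state[i]) j <- j + 1
    merged[[length(merged) + 1]] <- c(starts[i], ends[j], state[i])
    i <- j + 1
  }
  m <- do.call(rbind, merged)
  seg <- data.frame(
    start_frame = m[, 1], end_frame = m[, 2] + 1L,
    start_time = tm[m[, 1]], end_time = tm[m[, 2] + 1L],
    state = c("toward_start", "paused", "toward_goal")[m[, 3] + 2L],
    displacement = x[m[, 2] + 1L] - x[m[, 1]])
  dur <- seg$end_time - seg$start_time
  nxt_move <- c(seg$state[-1] != "paused", FALSE)
  seg$qualifies <- seg$state == "paused" & dur >= min_pause & nxt_move
  seg
}

#' Detect approach-avoid decision pauses
#'
#' One pause event per qualifying paused segment whose location (median
#' x during stillness) lies on the track proper; pauses inside the
#' Start or Goal box are excluded. The outcome is approach when the
#' first post-pause movement heads toward the goal, avoid when it heads
#' toward the start; RT is the pause duration (offset - onset). A pause
#' at the end of the session with no subsequent movement is dropped.
#'
#' @param segments output of [classify_motion].
#' @param trace the gap-filled [tracking_trace] the segments came from.
#' @param geometry a [track_geometry].
#' @return data.frame of pause events: `subject`, `session`, `onset_s`,
#'   `offset_s`, `rt_s`, `x_cm`, `zone`, `outcome`.
#' @export
detect_pauses <- function(segments, trace, geometry = track_geometry()) {
  keep <- which(segments$qualifies)
  out <- lapply(keep, function(i) {
    frames <- segments$start_frame[i]:segments$end_frame[i]
    loc <- stats::median(trace$x_cm[frames])
    if (loc < 0 || loc > geometry$track_len) return(NULL)
    nxt <- segments$state[i + 1]
    data.frame(
      subject = attr(trace, "subject_id") %||% "s1",
      session = attr(trace, "session_id") %||% "sess1",
      onset_s = segments$start_time[i],
      offset_s = segments$end_time[i],
      rt_s = segments$end_time[i] - segments$start_time[i],
      x_cm = loc,
      zone = zone_of(loc, geometry),
      outcome = if (nxt == "toward_goal") "approach" else "avoid")
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(subject = character(0), session = character(0),
                      onset_s = numeric(0), offset_s = numeric(0),
                      rt_s = numeric(0), x_cm = numeric(0),
                      zone = character(0), outcome = character(0)))
  }
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cluster spatial bins into decision zones
#'
#' Pauses are collated into `bin_width` (5 cm) bins over the track;
#' each non-empty bin contributes four features: median location, total
#' pause count, median pause duration, and % approach decisions.
#' Features are z-scored and clustered by k-means (50 restarts);
#' silhouette values are computed per bin. Zone boundaries are the
#' midpoints between adjacent bins assigned to different clusters when
#' the clusters are spatially contiguous; otherwise boundaries are
#' reported with a warning.
#'
#' @param pauses pause-event data.frame from [detect_pauses].
#' @param geometry a [track_geometry].
#' @param k number of zones (default 3).
#' @param seed k-means seed.
#' @return object of class `zone_partition`: list with `k`,
#'   `boundaries`, `bin_table`, `silhouette` (per bin), `mean_sil`,
#'   `min_sil`, `contiguous`.
#' @export
cluster_zones <- function(pauses, geometry = track_geometry(), k = 3,
                          seed = 1) {
  edges <- seq(0, geometry$track_len + geometry$bin_width - 1e-9,
               by = geometry$bin_width)
  edges[length(edges)] <- geometry$track_len
  on_track <- pauses$x_cm >= 0 & pauses$x_cm <= geometry$track_len
  p <- pauses[on_track, , drop = FALSE]
  bin <- cut(p$x_cm, edges, include.lowest = TRUE, labels = FALSE)
  tab <- do.call(rbind, lapply(sort(unique(bin)), function(bi) {
    sel <- bin == bi
    data.frame(bin = bi,
               med_x = stats::median(p$x_cm[sel]),
               n = sum(sel),
               med_rt = stats::median(p$rt_s[sel]),
               pct_approach = mean(p$outcome[sel] == "approach") * 100)
  }))
  if (nrow(tab) < k) stop("k exceeds the number of non-empty bins")
  if (k == 1) {
    return(structure(list(k = 1, boundaries = numeric(0),
                          bin_table = transform(tab, cluster = 1L),
                          silhouette = rep(NA_real_, nrow(tab)),
                          mean_sil = NA_real_, min_sil = NA_real_,
                          contiguous = TRUE),
                     class = "zone_partition"))
  }
  feat <- scale(as.matrix(tab[, c("med_x", "n", "med_rt",
                                  "pct_approach")]))
  feat[, apply(feat, 2, function(cc) any(!is.finite(cc)))] <- 0
  set.seed(seed)
  km <- stats::kmeans(feat, centers = k, nstart = 50)
  sil <- cluster::silhouette(km$cluster, stats::dist(feat))
  cl <- km$cluster
  tab$cluster <- cl
  ord <- order(tab$med_x)
  cl_o <- cl[ord]
  # contiguity: each cluster occupies one run of adjacent bins
  contiguous <- length(rle(cl_o)$values) == k
  cuts <- which(diff(cl_o) != 0)
  boundaries <- (tab$med_x[ord][cuts] + tab$med_x[ord][cuts + 1]) / 2
  if (!contiguous) {
    warning("zone clusters are not spatially contiguous; boundaries ",
            "reported at every cluster change along the track")
  }
  structure(list(k = k, boundaries = boundaries, bin_table = tab,
                 silhouette = as.numeric(sil[, "sil_width"]),
                 mean_sil = mean(sil[, "sil_width"]),
                 min_sil = min(sil[, "sil_width"]),
                 contiguous = contiguous),
            class = "zone_partition")
}

#' Summarize pause RT distributions
#'
#' Maximum-likelihood log-normal fit to pause durations, with an R^2
#' between the fitted density and the empirical histogram
#' (Freedman-Diaconis bins), and a test of coefficient-of-variation
#' linearity: per spatial bin, mean RT vs SD of RT are fit by least
#' squares and the slope and R^2 are returned (proportional mean-SD
#' scaling, i.e. constant CV, gives R^2 near 1).
#'
#' @param pauses pause-event data.frame; needs >= 20 events for the
#'   distribution fit (otherwise fit fields are `NA` and `flag` says
#'   why).
#' @param geometry a [track_geometry] for the spatial CV bins.
#' @return object of class `rt_summary`: list with `n`, `mu`, `sigma`,
#'   `r2_lognormal`, `cv_slope`, `cv_r2`, `bin_stats`, `flag`.
#' @export
summarize_rts <- function(pauses, geometry = track_geometry()) {
  d <- pauses$rt_s
  out <- list(n = length(d), mu = NA_real_, sigma = NA_real_,
              r2_lognormal = NA_real_, cv_slope = NA_real_,
              cv_r2 = NA_real_, bin_stats = NULL, flag = NULL)
  class(out) <- "rt_summary"
  if (length(d) < 20) { out$flag <- "fewer than 20 events"; return(out) }
  ld <- log(d)
  out$mu <- mean(ld)
  out$sigma <- sqrt(mean((ld - out$mu)^2)) # MLE (n denominator)
  if (out$sigma == 0) {
    out$flag <- "zero variance: histogram R^2 undefined"
  } else {
    h <- grDevices::nclass.FD(d)
    breaks <- seq(min(d), max(d), length.out = h + 1)
    hist <- graphics::hist(d, breaks = breaks, plot = FALSE)
    emp <- hist$density
    fit <- stats::dlnorm(hist$mids, out$mu, out$sigma)
    ss_res <- sum((emp - fit)^2)
    ss_tot <- sum((emp - mean(emp))^2)
    out$r2_lognormal <- max(0, min(1, 1 - ss_res / ss_tot))
  }
  # CV linearity across spatial bins
  edges <- seq(0, geometry$track_len + geometry$bin_width - 1e-9,
               by = geometry$bin_width)
  edges[length(edges)] <- geometry$track_len
  bin <- cut(pauses$x_cm, edges, include.lowest = TRUE, labels = FALSE)
  bs <- do.call(rbind, lapply(sort(unique(bin[!is.na(bin)])), function(bi) {
    sel <- which(bin == bi)
    if (length(sel) < 3) return(NULL)
    data.frame(bin = bi, mean_rt = mean(d[sel]), sd_rt = stats::sd(d[sel]))
  }))
  out$bin_stats <- bs
  if (!is.null(bs) && nrow(bs) >= 3 && stats::sd(bs$mean_rt) > 0) {
    fit <- stats::lm(sd_rt ~ mean_rt, data = bs)
    out$cv_slope <- unname(stats::coef(fit)[2])
    out$cv_r2 <- summary(fit)$r.squared
  }
  out
}

#' Per-session locomotor metrics
#'
#' Time in the Start box, on the track and in the Goal box; the
#' distance-from-goal and velocity (centered difference) series; and
#' the latency to first Goal-box entry.
#'
#' @param trace gap-filled [tracking_trace].
#' @param geometry a [track_geometry].
#' @return list with `time_start_box`, `time_track`, `time_goal_box`
#'   (s), `dist_from_goal`, `velocity` (cm/s, same length as the
#'   trace), `latency_to_goal` (s, `NA` if the goal is never reached).
#' @export
summarize_session <- function(trace, geometry = track_geometry()) {
  stopifnot(all(trace$valid))
  x <- trace$x_cm; tm <- trace$time_s
  n <- length(x)
  dt <- diff(tm)
  region <- ifelse(x < 0, "start_box",
                   ifelse(x > geometry$track_len, "goal_box", "track"))
  # frame dwell time: half-interval on each side (trapezoid allocation)
  w <- c(dt / 2, 0) + c(0, dt / 2)
  vel <- numeric(n)
  if (n >= 3) {
    vel[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (tm[3:n] - tm[1:(n - 2)])
  }
  vel[1] <- (x[2] - x[1]) / (tm[2] - tm[1])
  vel[n] <- (x[n] - x[n - 1]) / (tm[n] - tm[n - 1])
  goal_hit <- which(x > geometry$track_len)
  list(time_start_box = sum(w[region == "start_box"]),
       time_track = sum(w[region == "track"]),
       time_goal_box = sum(w[region == "goal_box"]),
       dist_from_goal = geometry$track_len - x,
       velocity = vel,
       latency_to_goal = if (length(goal_hit)) tm[goal_hit[1]] - tm[1]
                         else NA_real_)
}

#' Match detected pauses against a generative event list
#'
#' A detected pause matches a true pause of the same subject when its
#' onset lies within `tol_s` of the true onset. Reports recall (matched
#' true events / true events) and outcome agreement among matches.
#'
#' @param detected pause table from [detect_pauses] (rows across
#'   subjects allowed).
#' @param truth generative pause table (needs `subject`, `onset_s`,
#'   `outcome`).
#' @param tol_s onset matching tolerance, s (default one frame at
#'   30 fps).
#' @return list with `recall`, `outcome_agreement`, `n_true`,
#'   `n_detected`, `n_matched`.
#' @export
match_pauses <- function(detected, truth, tol_s = 1 / 30 + 1e-9) {
  n_true <- nrow(truth); n_match <- 0L; n_agree <- 0L
  for (sb in unique(truth$subject)) {
    tt <- truth[truth$subject == sb, , drop = FALSE]
    dd <- detected[detected$subject == sb, , drop = FALSE]
    if (!nrow(dd)) next
    for (i in seq_len(nrow(tt))) {
      j <- which.min(abs(dd$onset_s - tt$onset_s[i]))
      if (abs(dd$onset_s[j] - tt$onset_s[i]) <= tol_s) {
        n_match <- n_match + 1L
        if (dd$outcome[j] == tt$outcome[i]) n_agree <- n_agree + 1L
      }
    }
  }
  list(recall = n_match / n_true,
       outcome_agreement = if (n_match) n_agree / n_match else NA_real_,
       n_true = n_true, n_detected = nrow(detected),
       n_matched = n_match)
}
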