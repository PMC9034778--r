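# Fiber-photometry processing: isosbestic-corrected dF/F, peri-event
# kernels, bootstrap confidence bands with persistence-based
# significant epochs, spatial dF/F maps and pause-locked aggregates.
#
# dF/F is a fraction throughout; multiply by 100 for %dF/F at
# presentation.

#' Isosbestic-corrected dF/F
#'
#' The isosbestic channel is regressed onto the calcium channel by
#' ordinary least squares (isosbestic as predictor) to produce a fitted
#' isosbestic signal capturing shared artifacts; then
#' `dff = (ca - fitted) / fitted`.
#'
#' @param rec a `photometry_recording` (fields `time_s`, `ca_signal`,
#'   `iso_signal`, optionally `x_cm`), or any list with those fields.
#' @return object of class `dff_trace`: list with `time_s`, `dff`,
#'   `slope`, `intercept`, and `x_cm` if present.
#' @export
compute_dff <- function(rec) {
  ca <- rec$ca_signal; iso <- rec$iso_signal
  stopifnot(length(ca) == length(iso), length(ca) >= 100)
  if (stats::sd(iso) == 0) {
    stop("constant isosbestic channel: regression is degenerate")
  }
  fit <- stats::lm.fit(cbind(1, iso), ca)
  co <- fit$coefficients
  fitted <- co[1] + co[2] * iso
  structure(list(time_s = rec$time_s,
                 dff = (ca - fitted) / fitted,
                 slope = unname(co[2]), intercept = unname(co[1]),
                 x_cm = rec$x_cm),
            class = "dff_trace")
}

#' Peri-event dF/F kernels
#'
#' Extracts dF/F in a window around each event, resampled onto a
#' uniform time axis (default 20 Hz), and baselines each event
#' waveform to the mean of its baseline window. Events whose window is
#' not fully covered by the recording are dropped.
#'
#' @param dff a `dff_trace`.
#' @param events event timestamps, s.
#' @param window peri-event window, s (default `c(-5, 5)`).
#' @param baseline baseline window, s (default `c(-5, -2.5)`).
#' @param fs_out output sampling rate, Hz (default 20).
#' @return object of class `event_kernel`: list with `time` (axis),
#'   `waveforms` (events x time, baselined), `mean` waveform,
#'   `n_events`, `n_dropped`.
#' @export
extract_kernels <- function(dff, events, window = c(-5, 5),
                            baseline = c(-5, -2.5), fs_out = 20) {
  axis <- seq(window[1], window[2], by = 1 / fs_out)
  t0 <- min(dff$time_s); t1 <- max(dff$time_s)
  usable <- events[events + window[1] >= t0 & events + window[2] <= t1]
  n_drop <- length(events) - length(usable)
  if (!length(usable)) {
    return(structure(list(time = axis, waveforms = NULL, mean = NULL,
                          n_events = 0L, n_dropped = n_drop,
                          flag = "no usable events"),
                     class = "event_kernel"))
  }
  bidx <- axis >= baseline[1] & axis <= baseline[2]
  wf <- t(vapply(usable, function(ev) {
    w <- stats::approx(dff$time_s, dff$dff, xout = ev + axis,
                       rule = 1)$y
    w - mean(w[bidx])
  }, numeric(length(axis))))
  structure(list(time = axis, waveforms = wf, mean = colMeans(wf),
                 n_events = length(usable), n_dropped = n_drop),
            class = "event_kernel")
}

#' Bootstrap confidence band and significant epochs
#'
#' Resamples subject mean waveforms with replacement (`n_boot`
#' iterations), takes 2.5/97.5 percentiles of the bootstrap
#' distribution of the across-subject mean, and expands the band's
#' half-widths about the bootstrap mean by `sqrt(n / (n - 1))`. A
#' significant epoch is a maximal run of at least `min_run` consecutive
#' samples (default 7, about 1/3 s at 20 Hz) where the band excludes 0.
#'
#' @param waveforms matrix subjects x time of per-subject mean
#'   waveforms.
#' @param time time axis (s), one value per column.
#' @param n_boot bootstrap iterations (default 1000).
#' @param min_run persistence criterion in samples (default 7).
#' @param seed integer seed.
#' @return list with `mean`, `ci_lo`, `ci_hi`, `epochs` (data.frame
#'   start/end/sign), `n_subjects`, `expansion`.
#' @export
bootstrap_ci <- function(waveforms, time, n_boot = 1000, min_run = 7,
                         seed = 1) {
  stopifnot(is.matrix(waveforms), ncol(waveforms) == length(time))
  n <- nrow(waveforms)
  if (n < 2) stop("bootstrap requires at least 2 subjects")
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n_boot, n)
  boot_means <- t(apply(idx, 1, function(ii) colMeans(
    waveforms[ii, , drop = FALSE])))
  center <- colMeans(boot_means)
  lo <- apply(boot_means, 2, stats::quantile, 0.025)
  hi <- apply(boot_means, 2, stats::quantile, 0.975)
  expansion <- sqrt(n / (n - 1))
  ci_lo <- center - (center - lo) * expansion
  ci_hi <- center + (hi - center) * expansion
  sig <- sign(ci_lo) == sign(ci_hi) & ci_lo != 0 & ci_hi != 0 &
    (ci_lo > 0 | ci_hi < 0)
  r <- rle(as.vector(sig))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- which(r$values & r$lengths >= min_run)
  epochs <- if (length(keep)) {
    data.frame(start_s = time[starts[keep]], end_s = time[ends[keep]],
               sign = vapply(keep, function(i) {
                 if (mean(center[starts[i]:ends[i]]) > 0) "positive"
                 else "negative"
               }, character(1)))
  } else {
    data.frame(start_s = numeric(0), end_s = numeric(0),
               sign = character(0))
  }
  list(mean = colMeans(waveforms), ci_lo = ci_lo, ci_hi = ci_hi,
       epochs = epochs, n_subjects = n, expansion = expansion)
}

#' Spatial dF/F map in 5 cm bins
#'
#' Mean dF/F per spatial bin (samples assigned by their synchronized
#' track position), with zone aggregates over on-track bins. Empty
#' bins are `NA`, not zero.
#'
#' @param dff a `dff_trace` carrying `x_cm`.
#' @param geometry a [track_geometry].
#' @return list with `bin_edges`, `bin_mid`, `bin_mean`, and
#'   `zone_mean` (named: start, mid, goal).
#' @export
spatial_dff <- function(dff, geometry = track_geometry()) {
  stopifnot(!is.null(dff$x_cm))
  edges <- seq(0, geometry$track_len + geometry$bin_width - 1e-9,
               by = geometry$bin_width)
  edges[length(edges)] <- geometry$track_len
  x <- dff$x_cm
  on <- x >= 0 & x <= geometry$track_len
  bin <- cut(x[on], edges, include.lowest = TRUE, labels = FALSE)
  nb <- length(edges) - 1
  bm <- vapply(seq_len(nb), function(b) {
    v <- dff$dff[on][bin == b]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  zone <- zone_of((edges[-length(edges)] + edges[-1]) / 2, geometry)
  zm <- vapply(c("start", "mid", "goal"), function(z) {
    v <- bm[zone == z]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  list(bin_edges = edges, bin_mid = (edges[-length(edges)] + edges[-1]) / 2,
       bin_mean = bm, zone_mean = zm)
}

#' Mean dF/F during pauses
#'
#' Mean dF/F over each pause's [onset, offset] interval, with
#' per-subject-by-zone aggregates. Pauses outside the recording span
#' are dropped.
#'
#' @param dff a `dff_trace`.
#' @param pauses pause-event data.frame ([detect_pauses] output).
#' @return list with `per_pause` (the pause table plus `mean_dff`) and
#'   `per_zone` (data.frame subject, zone, mean_dff, n).
#' @export
pause_dff <- function(dff, pauses) {
  t0 <- min(dff$time_s); t1 <- max(dff$time_s)
  ok <- pauses$onset_s >= t0 & pauses$offset_s <= t1
  p <- pauses[ok, , drop = FALSE]
  p$mean_dff <- vapply(seq_len(nrow(p)), function(i) {
    sel <- dff$time_s >= p$onset_s[i] & dff$time_s <= p$offset_s[i]
    if (!any(sel)) return(NA_real_)
    mean(dff$dff[sel])
  }, numeric(1))
  p <- p[is.finite(p$mean_dff), , drop = FALSE]
  agg <- stats::aggregate(mean_dff ~ subject + zone, data = p, mean)
  agg$n <- stats::aggregate(mean_dff ~ subject + zone, data = p,
                            length)$mean_dff
  list(per_pause = p, per_zone = agg, n_dropped = sum(!ok))
}
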