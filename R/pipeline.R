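# End-to-end pipeline: simulate (optional) -> microstructure -> LBA
# fits -> photometry -> linkage, with a run manifest and per-stage
# counts. Also the CSV/JSON readers and writers for the documented
# external interfaces.

#' Read a tracking CSV
#'
#' Expected header: `frame, time_s, x_cm, y_cm, valid` (valid as 0/1).
#'
#' @param path CSV path.
#' @param subject_id,session_id identifiers attached to the trace.
#' @return a [tracking_trace].
#' @export
read_tracking_csv <- function(path, subject_id = "s1",
                              session_id = "sess1") {
  df <- utils::read.csv(path)
  stopifnot(all(c("frame", "time_s", "x_cm", "y_cm", "valid") %in%
                  names(df)))
  tracking_trace(df$time_s, df$x_cm, df$y_cm, valid = df$valid == 1,
                 subject_id = subject_id, session_id = session_id)
}

#' Write a tracking trace to CSV
#' @param trace a [tracking_trace].
#' @param path output path.
#' @export
write_tracking_csv <- function(trace, path) {
  df <- as.data.frame(trace)
  df$valid <- as.integer(df$valid)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a photometry CSV
#'
#' Expected header: `time_s, ca_465, iso_405, x_cm`.
#' @param path CSV path.
#' @return a `photometry_recording`-compatible list.
#' @export
read_photometry_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_s", "ca_465", "iso_405") %in% names(df)))
  structure(list(time_s = df$time_s, ca_signal = df$ca_465,
                 iso_signal = df$iso_405, x_cm = df$x_cm),
            class = "photometry_recording")
}

#' Write a photometry recording to CSV
#' @param rec a `photometry_recording`.
#' @param path output path.
#' @export
write_photometry_csv <- function(rec, path) {
  utils::write.csv(data.frame(time_s = rec$time_s,
                              ca_465 = rec$ca_signal,
                              iso_405 = rec$iso_signal,
                              x_cm = rec$x_cm),
                   path, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort (or consumes provided traces/recordings), then:
#' gap-fills and segments each trace, detects pauses, clusters spatial
#' bins into zones, fits the LBA per subject x zone, computes dF/F and
#' pause-locked aggregates, and builds the linkage table with the
#' correlation and regression summaries. Writes CSV/JSON artifacts and
#' a JSON manifest if `out_dir` is given.
#'
#' @param config a [cohort_config] (used to simulate when `traces` is
#'   `NULL`, and for geometry/frame-rate constants throughout).
#' @param traces optional named list of [tracking_trace] (one per
#'   subject); `NULL` to simulate.
#' @param recordings optional named list of photometry recordings
#'   aligned with `traces`.
#' @param sampler a [sampler_config] for the LBA fits.
#' @param min_trials minimum pauses per (subject, zone) LBA fit.
#' @param out_dir optional output directory for artifacts.
#' @param verbose print per-stage counts.
#' @return list of class `pipeline_report`: `pauses`, `zones`,
#'   `rt_summary`, `lba` (fit summary data.frame), `pause_dff`,
#'   `linkage`, `correlations`, `regression`, `directional`
#'   (named logicals: caution_goal_gt_mid, avoid_rt_gt_approach_goal,
#'   dff_caution_positive), `manifest`.
#' @export
run_pipeline <- function(config = cohort_config(), traces = NULL,
                         recordings = NULL,
                         sampler = sampler_config(),
                         min_trials = 20, out_dir = NULL,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  simulated <- is.null(traces)
  if (simulated) {
    say("stage simulate: %d subjects x %d trials (seed %d)",
        config$n_subjects, config$n_trials, config$seed)
    cohort <- simulate_cohort(config)
    traces <- cohort$traces
    recordings <- cohort$photometry
  }
  geom <- config$geometry
  # --- microstructure ---
  pauses <- list()
  for (sid in names(traces)) {
    tr <- interpolate_gaps(traces[[sid]])
    seg <- classify_motion(tr, geom)
    pauses[[sid]] <- detect_pauses(seg, tr, geom)
  }
  pauses <- do.call(rbind, pauses)
  rownames(pauses) <- NULL
  say("stage microstructure: %d pauses across %d subjects",
      nrow(pauses), length(traces))
  zones <- cluster_zones(pauses, geom)
  rts <- summarize_rts(pauses, geom)
  # --- LBA fits ---
  fits <- fit_per_zone(pauses, config = sampler, min_trials = min_trials)
  say("stage lba: %d fits, %d skipped", length(fits$fits),
      length(fits$skipped))
  # --- photometry ---
  pdff <- NULL
  if (!is.null(recordings)) {
    per_zone <- list()
    for (sid in names(recordings)) {
      d <- compute_dff(recordings[[sid]])
      pz <- pause_dff(d, pauses[pauses$subject == sid, , drop = FALSE])
      per_zone[[sid]] <- pz$per_zone
    }
    pdff <- do.call(rbind, per_zone)
    rownames(pdff) <- NULL
    say("stage photometry: %d (subject, zone) dF/F aggregates",
        nrow(pdff))
  }
  # --- linkage ---
  linkage <- NULL; correlations <- NULL; regression <- NULL
  directional <- c(caution_goal_gt_mid = NA,
                   avoid_rt_gt_approach = NA,
                   dff_caution_positive = NA)
  est <- fits$estimates
  if (!is.null(est)) {
    cg <- est$caution[est$zone == "goal"]
    cm <- est$caution[est$zone == "mid"]
    directional["caution_goal_gt_mid"] <-
      length(cg) > 0 && length(cm) > 0 && mean(cg) > mean(cm)
  }
  # avoid decisions slower than approach decisions, pooled across the
  # track (the per-zone race makes the locally dominant option the
  # conditionally faster one, so the comparison is across all pauses)
  if (any(pauses$outcome == "avoid") && any(pauses$outcome == "approach")) {
    directional["avoid_rt_gt_approach"] <-
      mean(pauses$rt_s[pauses$outcome == "avoid"]) >
      mean(pauses$rt_s[pauses$outcome == "approach"])
  }
  if (!is.null(pdff) && !is.null(est)) {
    linkage <- build_linkage_table(est, pdff)
    correlations <- lapply(
      stats::setNames(nm = c("v_approach", "v_avoid", "caution")),
      function(p) correlate_params(linkage, p))
    pvals <- vapply(correlations, `[[`, 0, "p")
    qvals <- stats::p.adjust(pvals, method = "BH")
    for (nm in names(correlations)) correlations[[nm]]$q <- qvals[[nm]]
    regression <- regress_dff(linkage)
    directional["dff_caution_positive"] <-
      isTRUE(correlations$caution$r > 0)
    say("stage linkage: %d rows; regression adj R2 = %.3f",
        nrow(linkage), regression$adj_r2)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("conflictlba")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    simulated = simulated,
    cohort_seed = config$seed,
    sampler_seed = sampler$seed,
    sampler = unclass(sampler),
    n_subjects = length(traces),
    n_pauses = nrow(pauses),
    min_trials = min_trials)
  report <- structure(
    list(pauses = pauses, zones = zones, rt_summary = rts,
         lba = est, lba_fits = fits, pause_dff = pdff,
         linkage = linkage, correlations = correlations,
         regression = regression, directional = directional,
         manifest = manifest),
    class = "pipeline_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write pipeline artifacts to a directory
#'
#' @param report a `pipeline_report`.
#' @param out_dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$pauses, file.path(out_dir, "pauses.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(k = report$zones$k, boundaries = report$zones$boundaries,
         mean_silhouette = report$zones$mean_sil,
         min_silhouette = report$zones$min_sil,
         contiguous = report$zones$contiguous),
    file.path(out_dir, "zones.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(report$lba)) {
    utils::write.csv(report$lba, file.path(out_dir, "lba_estimates.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$pause_dff)) {
    utils::write.csv(report$pause_dff,
                     file.path(out_dir, "pause_dff.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$linkage)) {
    utils::write.csv(as.data.frame(report$linkage),
                     file.path(out_dir, "linkage.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(regression = list(beta = as.list(report$regression$beta),
                             r2 = report$regression$r2,
                             adj_r2 = report$regression$adj_r2,
                             F = report$regression$F,
                             p = report$regression$p,
                             n = report$regression$n),
           correlations = lapply(report$correlations, function(cc)
             cc[c("r", "r2", "F", "p", "q", "n")]),
           directional = as.list(report$directional)),
      file.path(out_dir, "linkage_summary.json"),
      auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(report$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
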