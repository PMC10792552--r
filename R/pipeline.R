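# End-to-end orchestration: preprocess -> suppressions -> ratios -> spectral
# decomposition -> gamma -> events -> states, with optional on-disk output
# (CSV/JSON plus a manifest) and a reproducible result bundle.

#' Pipeline parameters
#'
#' All stage parameters with their standard defaults: relative IES
#' threshold 0.7, band-suppression threshold 0.2, strong-IES threshold 0.25
#' over 40 s, prominence thresholds theta 0.1 / delta 0.15 over 1 min,
#' 20 s ratio and power windows, 60 s spectral windows with 30 s step,
#' artifact hysteresis thresholds 0.08 / 1200 microvolts.
#'
#' @param suppression A [suppression_params()].
#' @param t_theta,t_delta Prominence thresholds.
#' @param spectral_width_s,spectral_step_s Spectral window grid.
#' @param power_width_s Power-ratio window width.
#' @param artifact_low,artifact_high Hysteresis artifact thresholds, uV.
#' @param gamma_persist_s,gamma_gap_tol_s Gamma-rebound detection.
#' @return A `pipeline_params` list.
#' @export
pipeline_params <- function(suppression = suppression_params(),
                            t_theta = 0.1, t_delta = 0.15,
                            spectral_width_s = 60, spectral_step_s = 30,
                            power_width_s = 20,
                            artifact_low = 0.08, artifact_high = 1200,
                            gamma_persist_s = 120, gamma_gap_tol_s = 1) {
  structure(list(suppression = suppression, t_theta = t_theta,
                 t_delta = t_delta, spectral_width_s = spectral_width_s,
                 spectral_step_s = spectral_step_s,
                 power_width_s = power_width_s, artifact_low = artifact_low,
                 artifact_high = artifact_high,
                 gamma_persist_s = gamma_persist_s,
                 gamma_gap_tol_s = gamma_gap_tol_s),
            class = "pipeline_params")
}

#' Run the full analysis pipeline on one recording
#'
#' Masks artifacts, segments IES and band suppressions, computes
#' suppression and band-power ratios, runs the sliding-window spectral
#' decomposition with rhythm tracking and the theta-decay fit, detects the
#' gamma rebound, assembles and validates the event chain, and labels the
#' anesthesia states. When `out_dir` is given, all stage outputs are
#' written (CSV/JSON) together with a manifest.
#'
#' @param rec A [ga_recording()], or a [scenario_config()] to simulate
#'   first (the ground truth is then attached to the result).
#' @param params A [pipeline_params()].
#' @param out_dir Optional output directory.
#' @return A `ga_analysis` list with elements `recording`, `ies`,
#'   `theta_supp`, `delta_supp`, `ies_sum`, `ratios` (power ratios),
#'   `prominence`, `frames`, `theta_track`, `delta_track`, `decay`,
#'   `gamma`, `events`, `order`, `states`, `truth` (simulated input only).
#' @export
run_pipeline <- function(rec, params = pipeline_params(), out_dir = NULL) {
  truth <- NULL
  if (inherits(rec, "scenario_config")) {
    sim <- assemble_recording(rec)
    truth <- sim$truth
    rec <- sim$recording
  }
  stopifnot(inherits(rec, "ga_recording"))
  stage <- "signal_io.mask_artifacts"
  res <- try({
    rec <- mask_artifacts(rec, params$artifact_low, params$artifact_high)
    stage <- "suppression.detect_ies"
    ies <- detect_ies(rec, params$suppression)
    theta_supp <- detect_band_suppressions(rec, "theta", ies,
                                           params$suppression)
    delta_supp <- detect_band_suppressions(rec, "delta", ies,
                                           params$suppression)
    ies_sum <- ies_summary(ies, rec, params$suppression)
    stage <- "spectral.power_ratios"
    ratios <- power_ratios(rec, params$power_width_s)
    prominence <- band_prominence_times(ratios, rec$annotations,
                                        params$t_theta, params$t_delta)
    stage <- "spectral.spectral_frames"
    frames <- spectral_frames(rec, params$spectral_width_s,
                              params$spectral_step_s)
    theta_track <- track_rhythms(frames, "theta")
    delta_track <- track_rhythms(frames, "delta")
    decay <- theta_decay(theta_track, frames, rec$annotations)
    stage <- "gamma.detect_gamma_rebound"
    pg <- gamma_power_series(rec)
    gam <- detect_gamma_rebound(pg, rec$annotations, params$gamma_persist_s,
                                params$gamma_gap_tol_s)
    gam$a_gamma <- gamma_area(pg, rec$annotations)
    stage <- "events_states.extract_event_chain"
    events <- extract_event_chain(ies_sum, prominence, decay, gam, rec)
    ord <- validate_order(events)
    states <- label_states(ratios, prominence, ies, events,
                           params$suppression$strong_thr,
                           params$suppression$strong_persist_s)
    list(recording = rec, ies = ies, theta_supp = theta_supp,
         delta_supp = delta_supp, ies_sum = ies_sum, ratios = ratios,
         prominence = prominence, frames = frames,
         theta_track = theta_track, delta_track = delta_track,
         decay = decay, gamma = gam, p_gamma = pg, events = events,
         order = ord, states = states, truth = truth)
  }, silent = TRUE)
  if (inherits(res, "try-error"))
    stop("pipeline stage ", stage, " failed: ",
         attr(res, "condition")$message)
  res <- structure(res, class = "ga_analysis")
  if (!is.null(out_dir)) write_analysis(res, out_dir, params)
  res
}

#' @export
print.ga_analysis <- function(x, ...) {
  cat("== anesthesia-state analysis ==\n")
  cat(sprintf("recording: %.1f s, %d IES segment(s), cumulative IES %.1f s\n",
              recording_duration(x$recording), nrow(x$ies),
              x$ies_sum$delta_ies))
  print(x$events)
  cat(if (x$order$ordered) "event chain: ordered\n"
      else sprintf("event chain: %d violation(s)\n", nrow(x$order$violations)))
  path <- rle(as.character(stats::na.omit(x$states$state)))$values
  cat("state path:", paste(path, collapse = " -> "), "\n")
  if (!is.na(x$gamma$tau_gamma))
    cat(sprintf("gamma rebound at %.1f s, area %.0f uV^2 s\n",
                x$gamma$tau_gamma, x$gamma$a_gamma))
  invisible(x)
}

# Write all stage outputs plus a manifest.
write_analysis <- function(res, out_dir, params) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seg_df <- function(seg, label) {
    if (nrow(seg) == 0)
      return(data.frame(label = character(0), start_s = numeric(0),
                        end_s = numeric(0)))
    data.frame(label = label, start_s = seg[, 1], end_s = seg[, 2])
  }
  utils::write.csv(rbind(seg_df(res$ies, "IES"),
                         seg_df(res$theta_supp, "thetaS"),
                         seg_df(res$delta_supp, "deltaS")),
                   file.path(out_dir, "segments.csv"), row.names = FALSE)
  utils::write.csv(data.frame(center_s = res$ies_sum$centers,
                              ies_ratio = res$ies_sum$ratio),
                   file.path(out_dir, "suppression_ratios.csv"),
                   row.names = FALSE)
  utils::write.csv(res$ratios, file.path(out_dir, "power_ratios.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(res$frames),
                   file.path(out_dir, "spectral_frames.csv"),
                   row.names = FALSE)
  utils::write.csv(res$states[, c("center_s", "state")],
                   file.path(out_dir, "states.csv"), row.names = FALSE)
  ev <- res$events
  jsonlite::write_json(ev[!vapply(ev, is.null, logical(1))],
                       file.path(out_dir, "events.json"), auto_unbox = TRUE,
                       na = "null", digits = NA)
  jsonlite::write_json(list(tau_gamma = res$gamma$tau_gamma,
                            t_gamma = res$gamma$t_gamma,
                            a_gamma = res$gamma$a_gamma),
                       file.path(out_dir, "gamma.json"), auto_unbox = TRUE,
                       na = "null", digits = NA)
  tracks <- lapply(list(theta = res$theta_track, delta = res$delta_track),
                   function(tr) list(
                     intervals = unname(apply(tr$valid_intervals, 1,
                                              function(r) c(r[1], r[2]),
                                              simplify = FALSE)),
                     knots = tr$knots))
  jsonlite::write_json(tracks, file.path(out_dir, "tracks.json"),
                       na = "null", digits = NA)
  manifest <- list(
    package = "anesmap",
    version = as.character(utils::packageVersion("anesmap")),
    created = format(Sys.time(), tz = "UTC"),
    params_hash = sum(utils::object.size(params)),
    n_samples = length(res$recording$eeg),
    fs = res$recording$fs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}
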