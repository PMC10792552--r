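# Segmentation of iso-electric suppressions (IES) and theta/delta band
# suppressions, suppression ratios on a sliding-window grid, and the derived
# IES timestamps (first occurrence, cumulative duration, strong-IES onset).
#
# "Amplitude" is the pointwise absolute value of the (raw or band-passed)
# signal; the >= 1 s duration rule makes sub-threshold half-cycle dips at
# zero crossings irrelevant.

#' Detection parameters for suppression analysis
#'
#' Defaults follow the method's standard parameter table: adaptive IES
#' threshold `r_ies * RMS`, band-suppression threshold `0.2 * RMS`, 1 s
#' minimum duration, 0.5 s merge gap, 20 s ratio windows with 10 s overlap,
#' strong-IES ratio threshold 0.25 persisting 40 s.
#'
#' @param r_ies Relative IES threshold (dimensionless).
#' @param band_thr Relative band-suppression threshold.
#' @param min_dur_s Minimum suppression duration in seconds.
#' @param merge_gap_s Suppressions separated by less than this merge.
#' @param theta_band,delta_band Band edges in Hz.
#' @param ratio_window_s,ratio_overlap_s Suppression-ratio grid.
#' @param strong_thr Strong-IES ratio threshold.
#' @param strong_persist_s Persistence required for the strong-IES onset.
#' @param baseline_rms_only If `TRUE`, the reference RMS is computed on
#'   `[0, tau_iso_start)` only (real-time variant); default uses the whole
#'   unmasked recording.
#' @return A `suppression_params` list.
#' @export
suppression_params <- function(r_ies = 0.7, band_thr = 0.2, min_dur_s = 1,
                               merge_gap_s = 0.5, theta_band = c(5, 10),
                               delta_band = c(2.5, 4.5), ratio_window_s = 20,
                               ratio_overlap_s = 10, strong_thr = 0.25,
                               strong_persist_s = 40,
                               baseline_rms_only = FALSE) {
  if (min_dur_s <= merge_gap_s || merge_gap_s < 0)
    stop_invalid("need min_dur_s > merge_gap_s >= 0")
  if (r_ies <= 0 || band_thr <= 0 || strong_thr <= 0)
    stop_invalid("thresholds must be positive")
  structure(list(r_ies = r_ies, band_thr = band_thr, min_dur_s = min_dur_s,
                 merge_gap_s = merge_gap_s, theta_band = theta_band,
                 delta_band = delta_band, ratio_window_s = ratio_window_s,
                 ratio_overlap_s = ratio_overlap_s, strong_thr = strong_thr,
                 strong_persist_s = strong_persist_s,
                 baseline_rms_only = baseline_rms_only),
            class = "suppression_params")
}

#' Detect sub-threshold suppression segments
#'
#' Maximal runs where `|x| < threshold` lasting at least `min_dur_s`
#' (masked samples never count as suppression); detected suppressions
#' separated by less than `merge_gap_s` are then merged into one. The
#' duration filter runs first: sub-threshold half-cycle dips of an ongoing
#' oscillation (a few tens of ms at EEG frequencies) are not detections,
#' so they can neither survive nor bridge a merge.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz.
#' @param threshold Amplitude threshold in microvolts (> 0).
#' @param min_dur_s Minimum segment duration, seconds.
#' @param merge_gap_s Merge gap, seconds.
#' @param mask Optional logical artifact mask.
#' @return Segment matrix (columns `start`, `end`), sorted and disjoint.
#' @export
detect_suppressions <- function(x, fs, threshold, min_dur_s = 1,
                                merge_gap_s = 0.5, mask = NULL) {
  if (length(x) == 0) stop_degenerate("empty signal")
  if (!is_scalar_num(threshold) || threshold <= 0)
    stop_invalid("threshold must be > 0")
  below <- abs(x) < threshold
  if (!is.null(mask)) below <- below & !mask
  seg <- runs_to_segments(below, fs)
  seg <- seg[segment_durations(seg) >= min_dur_s - 1e-9, , drop = FALSE]
  merge_segments(seg, gap = merge_gap_s)
}

# Reference RMS for the adaptive thresholds, with a floor of 0.01 uV so that
# an (almost) all-flat recording still yields a usable positive threshold.
reference_rms <- function(rec, params) {
  x <- rec$eeg
  mask <- rec$mask
  if (isTRUE(params$baseline_rms_only)) {
    t0 <- rec$annotations$tau_iso_start
    if (is.null(t0) || is.na(t0))
      stop_invalid("baseline_rms_only requires a tau_iso_start annotation")
    keep <- seq_len(max(1L, floor(t0 * rec$fs)))
    x <- x[keep]; mask <- mask[keep]
  }
  max(rms(x, mask), 0.01)
}

#' Detect iso-electric suppressions
#'
#' Applies [detect_suppressions()] to the raw EEG with the adaptive
#' threshold `r_ies * RMS` of the whole unmasked recording.
#'
#' @param rec A [ga_recording()].
#' @param params A [suppression_params()].
#' @export
detect_ies <- function(rec, params = suppression_params()) {
  thr <- params$r_ies * reference_rms(rec, params)
  detect_suppressions(rec$eeg, rec$fs, thr, params$min_dur_s,
                      params$merge_gap_s, rec$mask)
}

#' Detect theta- or delta-band suppressions
#'
#' Suppressions of the band-passed EEG at threshold `band_thr * RMS` of the
#' raw recording; any overlap with IES segments is removed (interval
#' difference) and the minimum-duration rule re-applied, so band
#' suppressions never intersect IES.
#'
#' @param rec A [ga_recording()].
#' @param band `"theta"` (5-10 Hz) or `"delta"` (2.5-4.5 Hz).
#' @param ies IES segments from [detect_ies()] on the same recording.
#' @param params A [suppression_params()].
#' @export
detect_band_suppressions <- function(rec, band = c("theta", "delta"), ies,
                                     params = suppression_params()) {
  band <- match.arg(band)
  edges <- if (band == "theta") params$theta_band else params$delta_band
  xf <- bandpass(rec$eeg, edges[1], edges[2], rec$fs)
  thr <- params$band_thr * reference_rms(rec, params)
  seg <- detect_suppressions(xf, rec$fs, thr, params$min_dur_s,
                             params$merge_gap_s, rec$mask)
  seg <- setdiff_segments(seg, ies)
  seg[segment_durations(seg) >= params$min_dur_s - 1e-9, , drop = FALSE]
}

#' Suppression ratio on a sliding-window grid
#'
#' For each window the ratio is the duration of segment overlap divided by
#' the window width, a value in `[0, 1]`. Windows whose masked fraction
#' exceeds `max_masked` are reported `NA`.
#'
#' @param segments Segment matrix (e.g. from [detect_ies()]).
#' @param grid A [make_grid()] grid (default convention: 20 s windows,
#'   10 s overlap).
#' @param mask Optional per-sample artifact mask.
#' @param fs Sampling rate (required with `mask`).
#' @param max_masked Masked-fraction cutoff above which a window is `NA`.
#' @return Numeric vector of ratios along `grid$centers`.
#' @export
suppression_ratios <- function(segments, grid, mask = NULL, fs = NULL,
                               max_masked = 0.5) {
  segments <- as_segments(segments)
  w <- grid$width_s
  out <- vapply(grid$centers, function(ct)
    overlap_duration(segments, ct - w / 2, ct + w / 2) / w, numeric(1))
  if (!is.null(mask) && any(mask)) {
    stopifnot(!is.null(fs))
    mf <- vapply(grid$centers, function(ct)
      window_masked_fraction(mask, ct, w, fs), numeric(1))
    out[mf > max_masked] <- NA_real_
  }
  out
}

# First center time (relative to t0) where ratio > thr on every window
# center within [t, t + persist_s]; NA ratios break the run; NA if never.
strong_onset_from_ratio <- function(ratio, centers, thr, persist_s, t0) {
  ok <- !is.na(ratio) & ratio > thr
  for (i in which(ok & centers >= t0)) {
    if (sustained_at(ok, centers, i, persist_s)) return(centers[i] - t0)
  }
  NA_real_
}

#' IES summary timestamps
#'
#' Returns the delay to the first IES occurrence, the cumulative IES
#' duration, and the strong-IES onset: the first time (after induction) at
#' which the IES ratio exceeds `strong_thr` on all 20 s windows spanning
#' `strong_persist_s`. Times are relative to `tau_iso_start`; absent events
#' are `NA`.
#'
#' @param ies IES segment matrix.
#' @param rec The [ga_recording()] the segments came from.
#' @param params A [suppression_params()].
#' @return List with `tau_ies1`, `delta_ies`, `tau_s`, and the ratio series
#'   (`ratio`, `centers`).
#' @export
ies_summary <- function(ies, rec, params = suppression_params()) {
  t0 <- rec$annotations$tau_iso_start %||% 0
  if (is.na(t0)) t0 <- 0
  ies <- as_segments(ies)
  grid <- make_grid(recording_duration(rec), params$ratio_window_s,
                    params$ratio_overlap_s)
  ratio <- suppression_ratios(ies, grid, rec$mask, rec$fs)
  list(
    tau_ies1 = if (nrow(ies)) unname(ies[1, 1]) - t0 else NA_real_,
    delta_ies = total_duration(ies),
    tau_s = strong_onset_from_ratio(ratio, grid$centers, params$strong_thr,
                                    params$strong_persist_s, t0),
    ratio = ratio, centers = grid$centers)
}

#' Sweep the relative IES threshold
#'
#' Detects IES for each relative threshold in `r_values` and reports the
#' total detected duration — the curve used by the threshold-selection
#' heuristic: a plateau in detected duration marks a robust threshold
#' choice.
#'
#' @param rec A [ga_recording()].
#' @param r_values Increasing positive relative thresholds.
#' @param params A [suppression_params()] (other fields than `r_ies` used).
#' @return `data.frame` with columns `r_ies` and `total_ies_s`.
#' @export
sweep_ies_threshold <- function(rec, r_values = seq(0.1, 2, by = 0.1),
                                params = suppression_params()) {
  if (any(diff(r_values) <= 0) || any(r_values < 0))
    stop_invalid("r_values must be increasing and non-negative")
  base <- reference_rms(rec, params)
  tot <- vapply(r_values, function(r) {
    if (r == 0) return(0)
    seg <- detect_suppressions(rec$eeg, rec$fs, r * base, params$min_dur_s,
                               params$merge_gap_s, rec$mask)
    total_duration(seg)
  }, numeric(1))
  data.frame(r_ies = r_values, total_ies_s = tot)
}
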