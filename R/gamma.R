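# Post-anesthesia gamma rebound: sustained narrow-band 50-70 Hz activity
# during recovery, detected against a baseline-derived power threshold and
# quantified by the area under the gamma-power curve.

#' Gamma-band power series
#'
#' Band-passes the EEG to 50-70 Hz and returns the mean squared amplitude
#' on contiguous 0.2 s windows (zero overlap), in microvolt^2.
#'
#' @param rec A [ga_recording()].
#' @param band Band edges in Hz.
#' @param width_s Window width in seconds.
#' @return `data.frame` with `center_s` and `p_gamma`.
#' @export
gamma_power_series <- function(rec, band = c(50, 70), width_s = 0.2) {
  if (rec$fs <= 2 * band[2]) stop_invalid("fs must exceed ", 2 * band[2],
                                          " Hz for the ", band[1], "-",
                                          band[2], " Hz band")
  xf <- bandpass(rec$eeg, band[1], band[2], rec$fs)
  nper <- round(width_s * rec$fs)
  nwin <- length(xf) %/% nper
  p <- colMeans(matrix(xf[1:(nwin * nper)]^2, nrow = nper))
  data.frame(center_s = (seq_len(nwin) - 0.5) * width_s, p_gamma = p)
}

#' Detect the gamma rebound
#'
#' The threshold is three times the RMS of the gamma-power series over the
#' pre-induction baseline `[0, tau_iso_start]`. A rebound is a run of
#' supra-threshold power sustained for at least `persist_s` during recovery
#' (`t > tau_iso_stop`); because the rebound is a train of intermittent
#' bursts, sub-threshold gaps shorter than `gap_tol_s` are tolerated
#' within a run.
#'
#' @param p_gamma A [gamma_power_series()] table.
#' @param annotations Needs `tau_iso_start` and `tau_iso_stop`.
#' @param persist_s Required persistence (default 2 min).
#' @param gap_tol_s Tolerated sub-threshold gap within a run, seconds.
#' @return List with `tau_gamma` (absolute onset time in seconds, `NA` when
#'   no rebound) and the threshold `t_gamma`.
#' @export
detect_gamma_rebound <- function(p_gamma, annotations, persist_s = 120,
                                 gap_tol_s = 1) {
  t0 <- annotations$tau_iso_start
  t1 <- annotations$tau_iso_stop
  if (is.null(t0) || is.na(t0) || is.null(t1) || is.na(t1))
    stop_invalid("tau_iso_start and tau_iso_stop annotations are required")
  base <- p_gamma$p_gamma[p_gamma$center_s <= t0]
  if (length(base) == 0) stop_invalid("empty baseline [0, tau_iso_start]")
  thr <- 3 * sqrt(mean(base^2))
  width <- stats::median(diff(p_gamma$center_s))
  rec_idx <- p_gamma$center_s > t1
  above <- rec_idx & p_gamma$p_gamma > thr
  seg <- runs_to_segments(above, 1 / width)      # segment times in units of
  seg <- merge_segments(seg, gap = gap_tol_s)    # the series' own clock
  seg <- seg[segment_durations(seg) >= persist_s, , drop = FALSE]
  tau <- if (nrow(seg)) seg[1, 1] else NA_real_
  list(tau_gamma = tau, t_gamma = thr)
}

#' Area under the gamma-power curve during recovery
#'
#' Trapezoidal integral of `p_gamma` from `tau_iso_stop` to the end of the
#' recording, in microvolt^2 seconds.
#'
#' @param p_gamma A [gamma_power_series()] table.
#' @param annotations Needs `tau_iso_stop`.
#' @export
gamma_area <- function(p_gamma, annotations) {
  t1 <- annotations$tau_iso_stop
  if (is.null(t1) || is.na(t1)) stop_invalid("tau_iso_stop is required")
  keep <- p_gamma$center_s >= t1
  t <- p_gamma$center_s[keep]; y <- p_gamma$p_gamma[keep]
  if (length(t) < 2) return(0)
  sum(diff(t) * (y[-1] + y[-length(y)]) / 2)
}
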