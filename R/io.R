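# Recording container, file input/output (EDF and columnar text), artifact
# masking, zero-phase filtering, RMS, and the sliding-window grid shared by
# all downstream analyses.
#
# Time convention: seconds from recording start; sample i covers the
# half-open interval [(i-1)/fs, i/fs); all segments are half-open.

#' EEG/EMG recording container
#'
#' Bundles a single-channel EEG trace (microvolts), an optional EMG trace,
#' the sampling rate, protocol annotations and a per-sample artifact mask.
#'
#' @param eeg Numeric vector, EEG in microvolts.
#' @param fs Sampling rate in Hz.
#' @param emg Optional numeric vector of the same length as `eeg`.
#' @param annotations Named list with protocol times in seconds:
#'   `tau_iso_start`, `tau_iso_stop` (anesthetic on/off) and optionally
#'   `tau_lom`, `tau_rom` (loss/return of movement, from the EMG).
#' @param mask Logical vector, `TRUE` marks unusable (artifact) samples.
#'   Defaults to all-`FALSE`.
#' @return An object of class `ga_recording`.
#' @export
ga_recording <- function(eeg, fs, emg = NULL, annotations = list(),
                         mask = NULL) {
  if (!is.numeric(eeg) || length(eeg) < 1)
    stop_invalid("eeg must be a non-empty numeric vector")
  if (!is_scalar_num(fs) || fs <= 0)
    stop_invalid("fs must be a positive number")
  if (!is.null(emg) && length(emg) != length(eeg))
    stop_invalid("emg and eeg must have the same length")
  if (is.null(mask)) mask <- rep(FALSE, length(eeg))
  if (length(mask) != length(eeg))
    stop_invalid("mask length must equal signal length")
  dur <- length(eeg) / fs
  for (nm in c("tau_iso_start", "tau_iso_stop", "tau_lom", "tau_rom")) {
    v <- annotations[[nm]]
    if (!is.null(v) && !is.na(v) && (v < 0 || v > dur))
      stop_invalid(nm, " = ", v, " lies outside the recording [0, ", dur, "]")
  }
  structure(list(eeg = as.numeric(eeg), emg = emg, fs = fs,
                 annotations = annotations, mask = as.logical(mask)),
            class = "ga_recording")
}

#' @export
print.ga_recording <- function(x, ...) {
  cat(sprintf("<ga_recording> %.1f s at %g Hz (%d samples)%s\n",
              recording_duration(x), x$fs, length(x$eeg),
              if (is.null(x$emg)) "" else ", with EMG"))
  ann <- x$annotations
  if (length(ann)) {
    shown <- vapply(names(ann), function(nm) {
      v <- ann[[nm]]
      sprintf("%s=%s", nm, if (is.null(v) || is.na(v)) "NA" else format(v))
    }, character(1))
    cat("  annotations:", paste(shown, collapse = ", "), "\n")
  }
  cat(sprintf("  masked: %.1f%% of samples\n", 100 * mean(x$mask)))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec A `ga_recording`.
#' @export
recording_duration <- function(rec) length(rec$eeg) / rec$fs

# ---- reading / writing ------------------------------------------------------

#' Read a recording from disk
#'
#' Supports 16-bit EDF files (channels named `EEG`/`EMG`) and two-column
#' UTF-8 text files `time_s value_uV` with a uniform time step, from which
#' the sampling rate is inferred. Protocol annotations can be supplied as a
#' JSON file `{"tau_iso_start": s, "tau_iso_stop": s, "tau_lom": s|null,
#' "tau_rom": s|null}`.
#'
#' @param path Path to the signal file.
#' @param format `"auto"` (by extension), `"edf"` or `"text"`.
#' @param annotations Optional path to an annotations JSON file, or a named
#'   list of annotation times.
#' @return A `ga_recording` with an all-false artifact mask.
#' @export
read_recording <- function(path, format = c("auto", "edf", "text"),
                           annotations = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "text"
  rec <- if (format == "edf") read_edf(path) else read_recording_text(path)
  ann <- annotations
  if (is.character(ann)) ann <- jsonlite::read_json(ann, simplifyVector = TRUE)
  if (!is.null(ann)) {
    ann <- lapply(ann, function(v) if (is.null(v)) NA_real_ else as.numeric(v))
    rec$annotations <- utils::modifyList(rec$annotations, ann)
  }
  rec
}

read_recording_text <- function(path) {
  tab <- utils::read.table(path, header = FALSE, col.names = c("t", "v"))
  if (nrow(tab) < 2) stop_invalid("text recording needs at least 2 samples")
  dt <- diff(tab$t)
  bad <- which(abs(dt - dt[1]) > 1e-6 * max(dt[1], 1e-12))
  if (length(bad))
    stop_invalid("irregular time step at row ", bad[1] + 1,
                 " (expected dt = ", signif(dt[1], 6), ")")
  if (dt[1] <= 0) stop_invalid("non-increasing time column")
  ga_recording(tab$v, fs = 1 / dt[1])
}

#' Write a recording as two-column text
#' @param rec A `ga_recording`.
#' @param path Output file.
#' @export
write_recording_text <- function(rec, path) {
  t <- (seq_along(rec$eeg) - 1) / rec$fs
  utils::write.table(data.frame(t = t, v = rec$eeg), path,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Minimal EDF (16-bit European Data Format) writer/reader for one or two
# channels. One data record per second; physical range set per channel from
# the data. Annotations travel in a side-car JSON, not in the EDF.
pad_field <- function(x, width) {
  s <- substr(sprintf("%-*s", width, as.character(x)), 1, width)
  s
}

#' Write a recording to an EDF file
#' @param rec A `ga_recording`. `fs` must be an integer number of samples per
#'   second; the trace is truncated to a whole number of 1-second records.
#' @param path Output path.
#' @export
write_edf <- function(rec, path) {
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop_invalid("EDF export requires an integer sampling rate")
  fs <- as.integer(round(fs))
  nrec <- length(rec$eeg) %/% fs
  if (nrec < 1) stop_invalid("recording shorter than one EDF record (1 s)")
  chans <- list(EEG = rec$eeg[1:(nrec * fs)])
  if (!is.null(rec$emg)) chans$EMG <- rec$emg[1:(nrec * fs)]
  ns <- length(chans)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field("synthetic", 80), pad_field("anesmap", 80),
    pad_field("01.01.26", 8), pad_field("00.00.00", 8),
    pad_field(256 * (1 + ns), 8), pad_field("", 44),
    pad_field(nrec, 8), pad_field("1", 8), pad_field(ns, 4))
  writeChar(hdr, con, eos = NULL)
  phys <- lapply(chans, function(x) {
    m <- max(abs(range(x)), 1e-3)
    c(-m, m)
  })
  field <- function(f, width) for (ch in names(chans))
    writeChar(pad_field(f(ch), width), con, eos = NULL)
  field(function(ch) ch, 16)                      # label
  field(function(ch) "", 80)                      # transducer
  field(function(ch) "uV", 8)                     # physical dimension
  field(function(ch) sprintf("%g", phys[[ch]][1]), 8)
  field(function(ch) sprintf("%g", phys[[ch]][2]), 8)
  field(function(ch) "-32768", 8)
  field(function(ch) "32767", 8)
  field(function(ch) "", 80)                      # prefiltering
  field(function(ch) fs, 8)                       # samples per record
  field(function(ch) "", 32)                      # reserved
  dig <- lapply(names(chans), function(ch) {
    p <- phys[[ch]]
    as.integer(round((chans[[ch]] - p[1]) / (p[2] - p[1]) * 65535 - 32768))
  })
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (k in seq_len(ns)) writeBin(dig[[k]][idx], con, size = 2,
                                    endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    s <- readChar(con, n, useBytes = TRUE)
    if (length(s) == 0) "" else s
  }
  num <- function(n) suppressWarnings(as.numeric(rd(n)))
  rd(8)                                   # version
  rd(160); rd(16)                         # ids, date, time
  num(8)                                  # header bytes
  rd(44)
  nrec <- num(8)
  recdur <- num(8)
  ns <- num(4)
  if (is.na(nrec) || is.na(ns) || ns < 1 || is.na(recdur) || recdur <= 0)
    stop_invalid("malformed EDF header in ", path)
  nrec <- as.integer(nrec); ns <- as.integer(ns)
  fields <- function(width) vapply(seq_len(ns),
                                   function(i) trimws(rd(width)), character(1))
  labels <- fields(16); fields(80); fields(8)
  pmin_ <- as.numeric(fields(8)); pmax_ <- as.numeric(fields(8))
  dmin_ <- as.numeric(fields(8)); dmax_ <- as.numeric(fields(8))
  fields(80)
  spr <- as.integer(fields(8)); fields(32)
  if (any(is.na(spr)) || any(spr <= 0))
    stop_invalid("EDF file missing samples-per-record (sampling rate)")
  dat <- vector("list", ns)
  for (k in seq_len(ns)) dat[[k]] <- integer(nrec * spr[k])
  for (r in seq_len(nrec)) {
    for (k in seq_len(ns)) {
      v <- readBin(con, "integer", n = spr[k], size = 2, endian = "little",
                   signed = TRUE)
      if (length(v) < spr[k]) stop_invalid("truncated EDF data in ", path)
      dat[[k]][((r - 1) * spr[k] + 1):(r * spr[k])] <- v
    }
  }
  scale <- (pmax_ - pmin_) / (dmax_ - dmin_)
  sig <- lapply(seq_len(ns),
                function(k) pmin_[k] + (dat[[k]] - dmin_[k]) * scale[k])
  names(sig) <- toupper(labels)
  eeg_k <- which(names(sig) == "EEG")
  if (length(eeg_k) == 0) eeg_k <- 1L
  emg_k <- which(names(sig) == "EMG")
  fs <- spr[eeg_k[1]] / recdur
  ga_recording(sig[[eeg_k[1]]], fs = fs,
               emg = if (length(emg_k)) sig[[emg_k[1]]] else NULL)
}

# ---- artifact masking -------------------------------------------------------

#' Mask recording artifacts
#'
#' Two rules, reported jointly in the updated per-sample mask: (1) dropout
#' runs where consecutive samples are exactly constant for at least
#' `min_flat_s` seconds; (2) high-amplitude excursions found by hysteresis
#' thresholding — every connected region with `|eeg| > low_thr` that touches
#' `|eeg| >= high_thr` is masked.
#'
#' @param rec A `ga_recording`.
#' @param low_thr Low hysteresis threshold in microvolts (default 0.08).
#' @param high_thr High hysteresis threshold in microvolts (default 1200).
#' @param min_flat_s Minimum duration of a constant run treated as dropout.
#' @return The recording with its artifact mask updated (old mask kept).
#' @export
mask_artifacts <- function(rec, low_thr = 0.08, high_thr = 1200,
                           min_flat_s = 0.5) {
  if (!is_scalar_num(low_thr) || !is_scalar_num(high_thr) ||
      low_thr <= 0 || low_thr >= high_thr)
    stop_invalid("need 0 < low_thr < high_thr")
  x <- rec$eeg
  n <- length(x)
  mask <- rec$mask
  # flat-line dropout: a run of k equal consecutive differences spans k + 1
  # equal samples
  if (n > 1) {
    r <- rle(diff(x) == 0)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & (r$lengths + 1L) >= min_flat_s * rec$fs)) {
      mask[starts[k]:(ends[k] + 1L)] <- TRUE
    }
  }
  # hysteresis: connected |x| > low regions containing |x| >= high
  above_low <- abs(x) > low_thr
  rr <- rle(above_low)
  e2 <- cumsum(rr$lengths); s2 <- e2 - rr$lengths + 1L
  for (k in which(rr$values)) {
    if (any(abs(x[s2[k]:e2[k]]) >= high_thr)) mask[s2[k]:e2[k]] <- TRUE
  }
  rec$mask <- mask
  rec
}

# ---- filtering and RMS ------------------------------------------------------

#' Zero-phase Butterworth band-pass filter
#'
#' Order-1 Butterworth applied forward and backward (`signal::filtfilt`,
#' effective order 4), so pass-band components keep their phase.
#'
#' @param x Numeric signal.
#' @param f1,f2 Band edges in Hz, `0 < f1 < f2 < fs/2`.
#' @param fs Sampling rate in Hz.
#' @export
bandpass <- function(x, f1, f2, fs) {
  if (!is_scalar_num(f1) || !is_scalar_num(f2) || f1 <= 0 || f2 <= f1 ||
      f2 >= fs / 2)
    stop_invalid("invalid band [", f1, ", ", f2, "] for fs = ", fs)
  bt <- signal::butter(1, c(f1, f2) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bt, x))
}

#' Zero-phase Butterworth low-pass filter
#' @param x Numeric signal.
#' @param f2 Cutoff in Hz.
#' @param fs Sampling rate in Hz.
#' @export
lowpass <- function(x, f2, fs) {
  if (!is_scalar_num(f2) || f2 <= 0 || f2 >= fs / 2)
    stop_invalid("invalid cutoff ", f2, " for fs = ", fs)
  bt <- signal::butter(1, f2 / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(bt, x))
}

#' Root mean square of the unmasked samples
#' @param x Numeric signal.
#' @param mask Optional logical vector; `TRUE` samples are excluded.
#' @export
rms <- function(x, mask = NULL) {
  if (!is.null(mask)) x <- x[!mask]
  if (length(x) == 0) stop_degenerate("all samples masked; RMS undefined")
  sqrt(mean(x^2))
}

# ---- sliding-window grid ----------------------------------------------------

#' Build a sliding-window grid
#'
#' Windows of width `width_s` centered at `width_s/2, width_s/2 + step, ...`
#' with `step = width_s - overlap_s`; only windows fully inside
#' `[0, duration_s]` are kept.
#'
#' @param duration_s Recording duration in seconds.
#' @param width_s Window width in seconds.
#' @param overlap_s Overlap between consecutive windows in seconds.
#' @return A `window_grid` list with `centers`, `width_s`, `overlap_s`.
#' @export
make_grid <- function(duration_s, width_s, overlap_s = 0) {
  if (!is_scalar_num(width_s) || !is_scalar_num(overlap_s) ||
      overlap_s < 0 || overlap_s >= width_s)
    stop_invalid("need 0 <= overlap_s < width_s")
  if (width_s > duration_s)
    stop_invalid("window width ", width_s, " exceeds duration ", duration_s)
  step <- width_s - overlap_s
  centers <- seq(width_s / 2, duration_s - width_s / 2 + 1e-9, by = step)
  structure(list(centers = centers, width_s = width_s, overlap_s = overlap_s),
            class = "window_grid")
}

#' @export
print.window_grid <- function(x, ...) {
  cat(sprintf("<window_grid> %d windows of %g s (overlap %g s), centers %g..%g s\n",
              length(x$centers), x$width_s, x$overlap_s,
              x$centers[1], x$centers[length(x$centers)]))
  invisible(x)
}

# Sample indices of the window centered at `center` (half-open in time).
window_indices <- function(center, width_s, fs, n) {
  i1 <- max(1L, floor((center - width_s / 2) * fs) + 1L)
  i2 <- min(n, round((center + width_s / 2) * fs))
  i1:i2
}

# Fraction of a window that is masked.
window_masked_fraction <- function(mask, center, width_s, fs) {
  idx <- window_indices(center, width_s, fs, length(mask))
  mean(mask[idx])
}
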