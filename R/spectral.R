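# Time-resolved spectral decomposition: Welch PSD on 5 s sub-windows,
# IRASA separation of the fractal (1/f-like) trend from oscillatory peaks,
# a corrected aperiodic fit a/(c + f^p) whose offset c keeps the model
# finite at f = 0, Gaussian parameterization of the oscillatory residual,
# rhythm tracking across sliding windows, and the theta-decay slope.

#' Welch power spectral density restricted to 0.2-15 Hz
#'
#' 5 s Hann sub-windows with 50% overlap give a 0.2 Hz frequency
#' resolution; the density is one-sided, in microvolt^2/Hz.
#'
#' @param x Signal window (at least `subwindow_s` long).
#' @param fs Sampling rate, Hz.
#' @param subwindow_s Welch sub-window length in seconds.
#' @param fmin,fmax Retained frequency range in Hz.
#' @return List with `freq` and `psd`.
#' @export
welch_psd <- function(x, fs, subwindow_s = 5, fmin = 0.2, fmax = 15) {
  nseg <- round(subwindow_s * fs)
  if (length(x) < nseg)
    stop_invalid("window shorter than the ", subwindow_s, " s sub-window")
  step <- nseg %/% 2
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(nseg - 1)) / (nseg - 1))   # Hann
  segs <- vapply(starts, function(s) x[s:(s + nseg - 1L)] * win,
                 numeric(nseg))
  ff <- stats::mvfft(segs)
  scale <- 1 / (fs * sum(win^2))
  pxx <- rowMeans(Mod(ff)^2) * scale
  # one-sided density (bins 2..nseg/2 doubled)
  nf <- nseg %/% 2
  psd <- pxx[2:(nf + 1)] * 2
  if (nseg %% 2 == 0) psd[nf] <- psd[nf] / 2
  freq <- (1:nf) * fs / nseg
  keep <- freq >= fmin - 1e-9 & freq <= fmax + 1e-9
  list(freq = freq[keep], psd = psd[keep])
}

# Fourier (band-limited) resampling of x to m samples, as used by the IRASA
# up/down-scaling: the spectrum is zero-padded or truncated symmetrically.
# m is nudged to the nearest 7-smooth length so the transforms stay fast;
# the realized scaling factor is m/length(x).
fft_resample <- function(x, m) {
  n <- length(x)
  m <- next_fast_len(m)
  if (m == n) return(x)
  X <- stats::fft(x)
  Y <- complex(length.out = m)
  kp <- (min(n, m) - 1L) %/% 2L
  Y[1] <- X[1]
  if (kp > 0) {
    Y[2:(kp + 1)] <- X[2:(kp + 1)]
    Y[(m - kp + 1):m] <- X[(n - kp + 1):n]
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' IRASA estimate of the fractal (1/f-like) PSD component
#'
#' The signal is up- and down-scaled by factors h in
#' `seq(hmin, hmax, hstep)` (Fourier resampling); for each pair the
#' geometric mean of the two Welch PSDs is taken on the common 0.2-15 Hz
#' grid, and the pointwise median across factors is the fractal estimate:
#' oscillatory peaks shift with h and are suppressed by the median while
#' the self-affine fractal part is invariant.
#'
#' @param x Signal window.
#' @param fs Sampling rate, Hz.
#' @param hmin,hmax,hstep Scaling-factor sweep (default 1.1-1.9 step 0.05,
#'   17 factors).
#' @return List with `freq` and `psd` (the median fractal PSD).
#' @export
irasa_aperiodic <- function(x, fs, hmin = 1.1, hmax = 1.9, hstep = 0.05) {
  n <- length(x)
  hs <- seq(hmin, hmax, by = hstep)
  base <- welch_psd(x, fs)
  gm <- matrix(NA_real_, nrow = length(base$freq), ncol = length(hs))
  for (i in seq_along(hs)) {
    up <- welch_psd(fft_resample(x, round(n * hs[i])), fs)$psd
    dn <- welch_psd(fft_resample(x, round(n / hs[i])), fs)$psd
    gm[, i] <- sqrt(up * dn)
  }
  list(freq = base$freq, psd = apply(gm, 1, stats::median))
}

#' Fit the corrected aperiodic model a / (c + f^p)
#'
#' Nonlinear least squares of `log PSD` against `log(a / (c + f^p))` with
#' `a > 0`, `c >= 0`, `p >= 0`. The amplitude is profiled out analytically;
#' `(c, p)` are optimized by bounded quasi-Newton from several starting
#' points.
#'
#' @param freq Frequency grid, Hz.
#' @param psd Strictly positive PSD values on `freq`.
#' @return List with `a`, `c`, `p`, `rss` (residual sum of squares in
#'   log-log) and `ok` (convergence flag).
#' @export
fit_aperiodic <- function(freq, psd) {
  if (any(!is.finite(psd)) || any(psd <= 0))
    return(list(a = NA_real_, c = NA_real_, p = NA_real_, rss = NA_real_,
                ok = FALSE))
  ly <- log(psd)
  obj <- function(par) {
    cc <- par[1]; pp <- par[2]
    lden <- log(cc + freq^pp)
    la <- mean(ly + lden)
    sum((ly - la + lden)^2)
  }
  hi <- freq >= 1
  slope <- -stats::coef(stats::lm(ly[hi] ~ log(freq[hi])))[2]
  p0 <- min(max(slope, 0), 8)
  best <- NULL
  for (c0 in c(0.01, 0.1, 1)) {
    fit <- try(stats::optim(c(c0, p0), obj, method = "L-BFGS-B",
                            lower = c(0, 0), upper = c(100, 10)),
               silent = TRUE)
    if (!inherits(fit, "try-error") &&
        (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best))
    return(list(a = NA_real_, c = NA_real_, p = NA_real_, rss = NA_real_,
                ok = FALSE))
  cc <- best$par[1]; pp <- best$par[2]
  la <- mean(ly + log(cc + freq^pp))
  list(a = exp(la), c = cc, p = pp, rss = best$value, ok = TRUE)
}

# Evaluate the aperiodic model on a frequency grid.
aperiodic_model <- function(fit, freq) fit$a / (fit$c + freq^fit$p)

#' Fit and select Gaussian oscillatory components
#'
#' The oscillatory residual (raw PSD minus the aperiodic fit, negative
#' values clipped to zero) is fitted on 1-15 Hz with a sum of up to
#' `max_peaks` Gaussians seeded at residual peaks of prominence at least
#' one residual standard deviation. Components with width outside
#' `[0.2, 2]` Hz or amplitude not exceeding the residual standard deviation
#' are discarded; at most one component is then selected per band (theta
#' 4-10 Hz, delta 2-4 Hz) by largest area `b * sigma`, ties broken by
#' proximity to the band median frequency (7.5 / 3 Hz), then by lower
#' center frequency.
#'
#' @param freq Frequency grid, Hz.
#' @param psd Raw PSD on `freq`.
#' @param ap_fit An aperiodic fit from [fit_aperiodic()].
#' @param max_peaks Maximum number of candidate Gaussians.
#' @return `data.frame` with columns `b`, `f`, `sigma`, `band` (zero rows
#'   when no component survives: no prominent rhythm in this window).
#' @export
fit_oscillatory <- function(freq, psd, ap_fit, max_peaks = 4) {
  none <- data.frame(b = numeric(0), f = numeric(0), sigma = numeric(0),
                     band = character(0), stringsAsFactors = FALSE)
  if (!isTRUE(ap_fit$ok)) return(none)
  keep <- freq >= 1
  f <- freq[keep]
  resid <- pmax(psd[keep] - aperiodic_model(ap_fit, f), 0)
  sd_r <- stats::sd(resid)
  if (!is.finite(sd_r) || sd_r == 0) return(none)
  # peak seeds: interior local maxima with height >= sd of the residual
  n <- length(resid)
  is_peak <- c(FALSE, resid[2:(n - 1)] >= resid[1:(n - 2)] &
                 resid[2:(n - 1)] >= resid[3:n], FALSE) & resid >= sd_r
  peaks <- which(is_peak)
  if (length(peaks) == 0) return(none)
  peaks <- peaks[order(resid[peaks], decreasing = TRUE)]
  sel <- integer(0)
  for (pk in peaks) {                      # enforce >= 1 Hz separation
    if (all(abs(f[pk] - f[sel]) >= 1) || length(sel) == 0)
      sel <- c(sel, pk)
    if (length(sel) >= max_peaks) break
  }
  k <- length(sel)
  par0 <- as.numeric(rbind(resid[sel], f[sel], rep(0.5, k)))
  lower <- rep(c(1e-12, 1, 0.1), k)
  upper <- rep(c(10 * max(resid), 15, 3), k)
  model <- function(par) {
    y <- numeric(length(f))
    for (j in seq_len(k)) {
      b <- par[3 * j - 2]; fc <- par[3 * j - 1]; s <- par[3 * j]
      y <- y + b * exp(-(f - fc)^2 / (2 * s^2))
    }
    y
  }
  fit <- try(stats::optim(par0, function(p) sum((resid - model(p))^2),
                          method = "L-BFGS-B", lower = lower, upper = upper,
                          control = list(maxit = 500)), silent = TRUE)
  par <- if (inherits(fit, "try-error")) par0 else fit$par
  comp <- data.frame(b = par[seq(1, 3 * k, 3)], f = par[seq(2, 3 * k, 3)],
                     sigma = par[seq(3, 3 * k, 3)],
                     stringsAsFactors = FALSE)
  comp <- comp[comp$sigma >= 0.2 & comp$sigma <= 2 & comp$b > sd_r, ,
               drop = FALSE]
  if (nrow(comp) == 0) return(none)
  comp$band <- ifelse(comp$f >= 4 & comp$f <= 10, "theta",
                      ifelse(comp$f >= 2 & comp$f < 4, "delta", "none"))
  out <- none
  for (bn in c("theta", "delta")) {
    cand <- comp[comp$band == bn, , drop = FALSE]
    if (nrow(cand) == 0) next
    med <- if (bn == "theta") 7.5 else 3
    area <- cand$b * cand$sigma
    o <- order(-area, abs(cand$f - med), cand$f)
    out <- rbind(out, cand[o[1], , drop = FALSE])
  }
  rownames(out) <- NULL
  out
}

#' Sliding-window spectral decomposition
#'
#' Runs Welch + IRASA + aperiodic fit + Gaussian parameterization on a
#' sliding grid (default 60 s windows, 30 s step). Windows that are more
#' than half masked, or whose aperiodic fit fails, are reported as missing
#' frames.
#'
#' @param rec A [ga_recording()].
#' @param width_s Window width in seconds.
#' @param step_s Step between window centers (width minus overlap).
#' @return `data.frame` of class `spectral_frames` with one row per window:
#'   `center_s`, aperiodic `a`, `c`, `p`, `rss`, and per band `b`, `f`,
#'   `sigma` (`NA` when no component was selected).
#' @export
spectral_frames <- function(rec, width_s = 60, step_s = 30) {
  grid <- make_grid(recording_duration(rec), width_s, width_s - step_s)
  n <- length(rec$eeg)
  rows <- lapply(grid$centers, function(ct) {
    row <- data.frame(center_s = ct, a = NA_real_, c = NA_real_, p = NA_real_,
                      rss = NA_real_, theta_b = NA_real_, theta_f = NA_real_,
                      theta_sigma = NA_real_, delta_b = NA_real_,
                      delta_f = NA_real_, delta_sigma = NA_real_)
    if (window_masked_fraction(rec$mask, ct, width_s, rec$fs) > 0.5)
      return(row)
    x <- rec$eeg[window_indices(ct, width_s, rec$fs, n)]
    raw <- welch_psd(x, rec$fs)
    frac <- irasa_aperiodic(x, rec$fs)
    ap <- fit_aperiodic(frac$freq, frac$psd)
    if (!isTRUE(ap$ok)) return(row)
    row$a <- ap$a; row$c <- ap$c; row$p <- ap$p; row$rss <- ap$rss
    comp <- fit_oscillatory(raw$freq, raw$psd, ap)
    for (bn in c("theta", "delta")) {
      ci <- comp[comp$band == bn, , drop = FALSE]
      if (nrow(ci)) {
        row[[paste0(bn, "_b")]] <- ci$b
        row[[paste0(bn, "_f")]] <- ci$f
        row[[paste0(bn, "_sigma")]] <- ci$sigma
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  attr(out, "width_s") <- width_s
  attr(out, "step_s") <- step_s
  class(out) <- c("spectral_frames", "data.frame")
  out
}

#' @export
print.spectral_frames <- function(x, ...) {
  cat(sprintf("<spectral_frames> %d windows (%g s wide, %g s step); %d with theta, %d with delta component\n",
              nrow(x), attr(x, "width_s"), attr(x, "step_s"),
              sum(!is.na(x$theta_f)), sum(!is.na(x$delta_f))))
  invisible(x)
}

#' Track a rhythm across spectral frames
#'
#' Center frequency and width are linearly interpolated between consecutive
#' frame detections; a detection whose two neighbors are both empty is
#' considered not significant and dropped. Envelopes are
#' `up(t) = f(t) + sigma(t)` and `low(t) = f(t) - sigma(t)`.
#'
#' @param frames A [spectral_frames()] table.
#' @param band `"theta"` or `"delta"`.
#' @return A `rhythm_track` list: `band`, `valid_intervals` (segment
#'   matrix), `knots` (`data.frame` of `t`, `f`, `sigma`), and functions
#'   `f_of_t`, `sigma_of_t`, `up`, `low` (`NA` outside valid intervals).
#' @export
track_rhythms <- function(frames, band = c("theta", "delta")) {
  band <- match.arg(band)
  fcol <- paste0(band, "_f"); scol <- paste0(band, "_sigma")
  det <- !is.na(frames[[fcol]])
  # drop isolated single-frame detections (neighbors outside the grid count
  # as not detected)
  nb_prev <- c(FALSE, det[-length(det)])
  nb_next <- c(det[-1], FALSE)
  det <- det & (nb_prev | nb_next)
  r <- rle(det)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  ivals <- empty_segments()
  knots <- data.frame(t = numeric(0), f = numeric(0), sigma = numeric(0))
  for (k in runs) {
    idx <- starts[k]:ends[k]
    ivals <- rbind(ivals, c(frames$center_s[idx[1]],
                            frames$center_s[idx[length(idx)]]))
    knots <- rbind(knots, data.frame(t = frames$center_s[idx],
                                     f = frames[[fcol]][idx],
                                     sigma = frames[[scol]][idx]))
  }
  ivals <- as_segments(ivals)
  in_valid <- function(t) {
    if (nrow(ivals) == 0) return(rep(FALSE, length(t)))
    vapply(t, function(ti)
      any(ti >= ivals[, 1] - 1e-9 & ti <= ivals[, 2] + 1e-9), logical(1))
  }
  interp <- function(col) {
    function(t) {
      if (nrow(knots) < 1) return(rep(NA_real_, length(t)))
      v <- stats::approx(knots$t, knots[[col]], xout = t, rule = 1)$y
      v[!in_valid(t)] <- NA_real_
      v
    }
  }
  f_of_t <- interp("f"); sigma_of_t <- interp("sigma")
  structure(list(band = band, valid_intervals = ivals, knots = knots,
                 f_of_t = f_of_t, sigma_of_t = sigma_of_t,
                 up = function(t) f_of_t(t) + sigma_of_t(t),
                 low = function(t) f_of_t(t) - sigma_of_t(t)),
            class = "rhythm_track")
}

#' @export
print.rhythm_track <- function(x, ...) {
  cat(sprintf("<rhythm_track> %s: %d valid interval(s), %d knot(s)\n",
              x$band, nrow(x$valid_intervals), nrow(x$knots)))
  invisible(x)
}

#' Theta-decay onset and slope
#'
#' The decay onset is the first frame center after induction whose tracked
#' theta frequency exceeds every later tracked value within the next
#' `horizon_s` (strict inequality, evaluated on frame centers; frames
#' without a theta detection are skipped, and a candidate whose horizon
#' extends past the last frame cannot be verified). The slope is the
#' least-squares slope of the tracked frequency over the 2 min after the
#' onset, in Hz/min (absent when fewer than 3 frames are available).
#'
#' @param track A theta [track_rhythms()] track.
#' @param frames The [spectral_frames()] the track came from.
#' @param annotations Recording annotations (needs `tau_iso_start`).
#' @param horizon_s Decay-persistence horizon in seconds (default 5 min).
#' @param slope_window_s Regression window in seconds (default 2 min).
#' @return List with `tau_theta_decay` (s, relative to `tau_iso_start`) and
#'   `slope_hz_per_min`, both `NA` when undetermined.
#' @export
theta_decay <- function(track, frames, annotations, horizon_s = 300,
                        slope_window_s = 120) {
  t0 <- annotations$tau_iso_start
  if (is.null(t0) || is.na(t0)) stop_invalid("tau_iso_start is required")
  centers <- frames$center_s
  fth <- track$f_of_t(centers)
  last_c <- max(centers)
  tau <- NA_real_
  for (i in which(centers > t0 & !is.na(fth))) {
    if (centers[i] + horizon_s > last_c + 1e-9) break  # unverifiable tail
    later <- which(centers > centers[i] &
                     centers <= centers[i] + horizon_s & !is.na(fth))
    if (length(later) == 0) next
    if (all(fth[later] < fth[i])) { tau <- centers[i]; break }
  }
  if (is.na(tau))
    return(list(tau_theta_decay = NA_real_, slope_hz_per_min = NA_real_))
  win <- which(centers >= tau & centers <= tau + slope_window_s &
                 !is.na(fth))
  slope <- if (length(win) >= 3) {
    stats::coef(stats::lm(fth[win] ~ centers[win]))[2] * 60
  } else NA_real_
  list(tau_theta_decay = tau - t0, slope_hz_per_min = unname(slope))
}

# ---- band-power ratios ------------------------------------------------------

#' Theta- and delta-band power ratios
#'
#' Computed directly on the EEG without the spectral decomposition: the
#' signal is band-passed (theta 5-10 Hz, delta 2.5-4.5 Hz) and low-passed
#' below 20 Hz; per window the ratio is the band power over the < 20 Hz
#' power. Windows more than half masked, or with (near-)zero low-pass
#' power, are `NA`.
#'
#' @param rec A [ga_recording()].
#' @param width_s Window width in seconds (20 s, no overlap).
#' @param theta_band,delta_band Band edges in Hz.
#' @return `data.frame` with `center_s`, `p_theta`, `p_delta`.
#' @export
power_ratios <- function(rec, width_s = 20, theta_band = c(5, 10),
                         delta_band = c(2.5, 4.5)) {
  if (rec$fs <= 40) stop_invalid("fs must exceed 40 Hz")
  grid <- make_grid(recording_duration(rec), width_s, 0)
  s20 <- lowpass(rec$eeg, 20, rec$fs)
  sth <- bandpass(rec$eeg, theta_band[1], theta_band[2], rec$fs)
  sde <- bandpass(rec$eeg, delta_band[1], delta_band[2], rec$fs)
  n <- length(rec$eeg)
  res <- t(vapply(grid$centers, function(ct) {
    idx <- window_indices(ct, width_s, rec$fs, n)
    if (mean(rec$mask[idx]) > 0.5) return(c(NA_real_, NA_real_))
    idx <- idx[!rec$mask[idx]]
    den <- mean(s20[idx]^2)
    if (!is.finite(den) || den < 1e-12) return(c(NA_real_, NA_real_))
    c(mean(sth[idx]^2) / den, mean(sde[idx]^2) / den)
  }, numeric(2)))
  data.frame(center_s = grid$centers, p_theta = res[, 1], p_delta = res[, 2])
}

# First center time (relative to t0) at which `cond` holds on every window
# center within [t, t + persist_s]; search starts at `from`.
first_sustained <- function(cond, centers, persist_s, t0, from = t0) {
  ok <- !is.na(cond) & cond
  for (i in which(centers >= from & ok)) {
    if (sustained_at(ok, centers, i, persist_s)) return(centers[i] - t0)
  }
  NA_real_
}

#' Band appearance and dampening times
#'
#' Delta appearance is the first time after induction with `P_delta > 0.15`
#' sustained for 1 min; theta (delta) dampening the first time with the
#' ratio below its threshold (theta 0.1, delta 0.15) sustained for 1 min,
#' the delta dampening searched from the delta appearance on. All times are
#' relative to `tau_iso_start`; `NA` when the condition never holds (delta
#' dampening is `NA` whenever delta never appeared).
#'
#' Also returns per-window prominence flags obtained by hysteresis: a
#' rhythm becomes prominent when its ratio exceeds the threshold for 1 min
#' and dampened when it stays below for 1 min, keeping its previous status
#' in between.
#'
#' @param ratios A [power_ratios()] table.
#' @param annotations Recording annotations (needs `tau_iso_start`).
#' @param t_theta,t_delta Prominence thresholds.
#' @param persist_s Persistence requirement in seconds.
#' @return List with `tau_delta_app`, `tau_theta_disp`, `tau_delta_disp`,
#'   and logical vectors `theta_prominent`, `delta_prominent` along
#'   `ratios$center_s`.
#' @export
band_prominence_times <- function(ratios, annotations, t_theta = 0.1,
                                  t_delta = 0.15, persist_s = 60) {
  t0 <- annotations$tau_iso_start
  if (is.null(t0) || is.na(t0)) stop_invalid("tau_iso_start is required")
  centers <- ratios$center_s
  tau_delta_app <- first_sustained(ratios$p_delta > t_delta, centers,
                                   persist_s, t0)
  tau_theta_disp <- first_sustained(ratios$p_theta < t_theta, centers,
                                    persist_s, t0)
  tau_delta_disp <- if (is.na(tau_delta_app)) NA_real_ else
    first_sustained(ratios$p_delta < t_delta, centers, persist_s, t0,
                    from = t0 + tau_delta_app)
  list(tau_delta_app = tau_delta_app, tau_theta_disp = tau_theta_disp,
       tau_delta_disp = tau_delta_disp,
       theta_prominent = prominence_flags(ratios$p_theta, t_theta, centers,
                                          persist_s),
       delta_prominent = prominence_flags(ratios$p_delta, t_delta, centers,
                                          persist_s))
}

# Hysteresis prominence status per window: switches on (off) at the start
# of a >= persist_s run above (below) the threshold; NA ratios break runs
# and keep the current status. Initial status comes from the first window.
prominence_flags <- function(p, thr, centers, persist_s = 60) {
  n <- length(p)
  status <- logical(n)
  cur <- !is.na(p[1]) && p[1] > thr
  above <- !is.na(p) & p > thr
  below <- !is.na(p) & p < thr
  for (i in seq_len(n)) {
    if (!cur && sustained_at(above, centers, i, persist_s)) cur <- TRUE
    else if (cur && sustained_at(below, centers, i, persist_s)) cur <- FALSE
    status[i] <- cur
  }
  status
}
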