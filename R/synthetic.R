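# Seeded synthetic EEG/EMG generator with known ground truth. Scenarios are
# ordered stage lists (awake, theta decay, prominent delta, suppression,
# recovery...) that tile the recording; each stage contributes an aperiodic
# 1/f-like background a/(c + f^p), optional narrow-band theta/delta rhythms,
# optional planted iso-electric suppressions, and an optional ~60 Hz gamma
# burst train. Stages are crossfaded (equal power) over 1 s; ground-truth
# event times refer to the nominal, un-faded boundaries.

#' Generate an aperiodic (1/f-like) background signal
#'
#' White Gaussian noise shaped in the frequency domain so that the expected
#' one-sided power spectral density equals `a / (c + f^p)` in
#' microvolt^2/Hz over (0, fs/2). The offset `c` keeps the PSD finite at
#' `f = 0`; `p = 0` yields white noise.
#'
#' @param a Amplitude of the PSD model (> 0).
#' @param c_ PSD offset (>= 0).
#' @param p Spectral exponent (>= 0).
#' @param duration_s Signal duration in seconds (>= 1/fs).
#' @param fs Sampling rate in Hz.
#' @param seed Optional integer seed; the same seed gives identical output.
#' @return Zero-mean numeric vector of length `round(duration_s * fs)`.
#' @export
generate_aperiodic <- function(a, c_, p, duration_s, fs, seed = NULL) {
  if (!is_scalar_num(a) || a <= 0) stop_invalid("a must be > 0")
  if (!is_scalar_num(c_) || c_ < 0) stop_invalid("c must be >= 0")
  if (!is_scalar_num(p) || p < 0) stop_invalid("p must be >= 0")
  if (!is_scalar_num(fs) || fs <= 0) stop_invalid("fs must be > 0")
  if (!is_scalar_num(duration_s) || duration_s < 1 / fs)
    stop_invalid("duration_s must be at least one sample (1/fs)")
  n <- round(duration_s * fs)
  with_seed(seed, {
    X <- complex(length.out = n)
    nf <- (n - 1) %/% 2
    if (nf > 0) {
      f <- (1:nf) * fs / n
      amp <- sqrt(a / (c_ + f^p) * fs * n / 2)
      z <- complex(real = stats::rnorm(nf), imaginary = stats::rnorm(nf)) /
        sqrt(2)
      X[2:(nf + 1)] <- amp * z
      X[n:(n - nf + 1)] <- Conj(X[2:(nf + 1)])
    }
    if (n %% 2 == 0 && n >= 2) {
      fny <- fs / 2
      X[n / 2 + 1] <- sqrt(a / (c_ + fny^p) * fs * n / 2) * stats::rnorm(1)
    }
    Re(stats::fft(X, inverse = TRUE)) / n
  })
}

#' Describe a narrow-band rhythm
#'
#' @param amplitude Peak amplitude in microvolts (>= 0; 0 gives silence).
#' @param f0 Center frequency at the start of the interval, Hz.
#' @param f1 Center frequency at the end (defaults to `f0`; a different
#'   value gives a linear chirp, e.g. the theta decay after induction).
#' @param sigma Spectral width (standard deviation of the line shape), Hz.
#' @return A `band_spec` list.
#' @export
band_spec <- function(amplitude, f0, f1 = f0, sigma = 0) {
  if (!is_scalar_num(amplitude) || amplitude < 0)
    stop_invalid("amplitude must be >= 0")
  if (!is_scalar_num(sigma) || sigma < 0) stop_invalid("sigma must be >= 0")
  structure(list(amplitude = amplitude, f0 = f0, f1 = f1, sigma = sigma),
            class = "band_spec")
}

#' Generate a narrow-band oscillation
#'
#' The instantaneous frequency follows the (constant or linearly chirping)
#' trajectory of the `band_spec`, jittered by slow Gaussian frequency
#' modulation so that the spectral line has width approximately `sigma`.
#'
#' @param spec A [band_spec()].
#' @param duration_s Duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param seed Optional integer seed (controls phase and frequency jitter).
#' @export
generate_oscillation <- function(spec, duration_s, fs, seed = NULL) {
  stopifnot(inherits(spec, "band_spec"))
  if (!is_scalar_num(duration_s) || duration_s < 1 / fs)
    stop_invalid("duration_s must be at least one sample (1/fs)")
  n <- round(duration_s * fs)
  lo <- min(spec$f0, spec$f1); hi <- max(spec$f0, spec$f1)
  if (lo <= 0 || hi >= fs / 2)
    stop_invalid("frequency trajectory [", lo, ", ", hi,
                 "] must stay inside (0, ", fs / 2, ")")
  if (spec$amplitude == 0) return(numeric(n))
  with_seed(seed, {
    f_traj <- seq(spec$f0, spec$f1, length.out = n)
    if (spec$sigma > 0) {
      # slow (~0.5 Hz) unit-variance modulation => approximately Gaussian
      # line shape with standard deviation sigma
      z <- stats::rnorm(n)
      bt <- signal::butter(2, min(0.5 / (fs / 2), 0.99), type = "low")
      z <- as.numeric(signal::filtfilt(bt, z))
      z <- z / max(stats::sd(z), 1e-12)
      f_inst <- f_traj + spec$sigma * z
    } else f_inst <- f_traj
    f_inst <- pmin(pmax(f_inst, 1e-3), fs / 2 - 1e-3)
    phase <- 2 * pi * cumsum(f_inst) / fs + stats::runif(1, 0, 2 * pi)
    spec$amplitude * sin(phase)
  })
}

#' Describe one scenario stage
#'
#' @param start_s,end_s Nominal stage interval, half-open `[start_s, end_s)`.
#' @param aperiodic Numeric `c(a, c, p)` of the background PSD model.
#' @param theta,delta Optional [band_spec()] rhythms.
#' @param ies_fraction Target fraction of the stage spent in planted
#'   near-flat iso-electric suppression (0 disables).
#' @param gamma Optional gamma burst train: list with `amplitude`, `center`
#'   (Hz, ~60), `sigma` (Hz), `on_s`, `off_s` (burst duty cycle).
#' @param emg_active Logical, kept for bookkeeping; the EMG switch times are
#'   taken from the scenario-level `tau_lom`/`tau_rom`.
#' @return A `stage_spec` list.
#' @export
stage_spec <- function(start_s, end_s, aperiodic = c(a = 100, c = 1, p = 2),
                       theta = NULL, delta = NULL, ies_fraction = 0,
                       gamma = NULL, emg_active = TRUE) {
  if (!is_scalar_num(start_s) || !is_scalar_num(end_s) || end_s <= start_s)
    stop_invalid("need start_s < end_s")
  if (!is.numeric(aperiodic) || length(aperiodic) != 3)
    stop_invalid("aperiodic must be c(a, c, p)")
  if (!is_scalar_num(ies_fraction) || ies_fraction < 0 || ies_fraction > 1)
    stop_invalid("ies_fraction must be in [0, 1]")
  structure(list(start_s = start_s, end_s = end_s,
                 aperiodic = as.numeric(aperiodic), theta = theta,
                 delta = delta, ies_fraction = ies_fraction, gamma = gamma,
                 emg_active = isTRUE(emg_active)),
            class = "stage_spec")
}

#' Scenario configuration for the synthetic generator
#'
#' @param fs Sampling rate in Hz; must exceed twice the highest planted
#'   frequency.
#' @param duration_s Total recording length in seconds.
#' @param tau_iso_start,tau_iso_stop Anesthetic on/off times in seconds.
#' @param stages List of [stage_spec()]s tiling `[0, duration_s)`.
#' @param seed Integer RNG seed for the whole scenario.
#' @param tau_lom,tau_rom Optional loss/return-of-movement times for the EMG.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(fs, duration_s, tau_iso_start, tau_iso_stop,
                            stages, seed = 1, tau_lom = NA, tau_rom = NA) {
  if (!(0 <= tau_iso_start && tau_iso_start < tau_iso_stop &&
        tau_iso_stop <= duration_s))
    stop_invalid("need 0 <= tau_iso_start < tau_iso_stop <= duration_s")
  starts <- vapply(stages, `[[`, numeric(1), "start_s")
  ends <- vapply(stages, `[[`, numeric(1), "end_s")
  o <- order(starts)
  stages <- stages[o]; starts <- starts[o]; ends <- ends[o]
  if (abs(starts[1]) > 1e-9 || abs(ends[length(ends)] - duration_s) > 1e-9 ||
      (length(stages) > 1 && any(abs(starts[-1] - ends[-length(ends)]) > 1e-9)))
    stop_invalid("stages must tile [0, duration_s) without gaps or overlap")
  fmax <- 0
  for (st in stages) {
    for (b in list(st$theta, st$delta))
      if (!is.null(b)) fmax <- max(fmax, b$f0, b$f1)
    if (!is.null(st$gamma)) fmax <- max(fmax, st$gamma$center)
  }
  if (fs <= 2 * fmax)
    stop_invalid("fs = ", fs, " must exceed twice the highest planted ",
                 "frequency (", fmax, " Hz)")
  structure(list(fs = fs, duration_s = duration_s,
                 tau_iso_start = tau_iso_start, tau_iso_stop = tau_iso_stop,
                 stages = stages, seed = seed, tau_lom = tau_lom,
                 tau_rom = tau_rom),
            class = "scenario_config")
}

# Equal-power crossfade envelope for a stage generated on an extended
# interval [s - pad, e + pad): unity inside, sine/cosine ramps at the edges.
crossfade_envelope <- function(n, ramp_in, ramp_out) {
  env <- rep(1, n)
  if (ramp_in > 0) {
    k <- min(ramp_in, n)
    env[1:k] <- sin(seq(0, pi / 2, length.out = k))
  }
  if (ramp_out > 0) {
    k <- min(ramp_out, n)
    env[(n - k + 1):n] <- cos(seq(0, pi / 2, length.out = k))
  }
  env
}

# Plant near-flat IES segments inside [start_s, end_s) hitting the target
# fraction. Alternating flat/active cycles of ~10 s; flat lengths jittered
# with zero-sum noise so the realized total matches frac * stage length.
plan_ies_segments <- function(start_s, end_s, frac) {
  len <- end_s - start_s
  k <- max(1L, round(len / 10))
  cycle <- len / k
  flat <- frac * cycle
  scale <- min(1, flat - 1.2, cycle - flat - 2.5)
  jit <- if (scale > 0 && k > 1) {
    u <- stats::runif(k, -1, 1)
    (u - mean(u)) * scale
  } else rep(0, k)
  fl <- flat + jit
  st <- start_s + (seq_len(k) - 1) * cycle + (cycle - fl) / 2
  as_segments(cbind(st, st + fl))
}

#' Assemble a synthetic recording with ground truth
#'
#' Sums, stage by stage, the aperiodic background, the planted rhythms and
#' the gamma burst train; realizes planted IES as near-flat traces (signal
#' scaled to 2% inside the planted segments); builds an EMG that switches
#' from active (band-limited 20-200 Hz noise) to 5% amplitude between
#' `tau_lom` and `tau_rom`; and reports the ground truth: planted IES
#' segments, per-band rhythm trajectories, the event timestamps implied by
#' the nominal stage boundaries, the planted gamma-power area, and the
#' movement switch times.
#'
#' @param config A [scenario_config()].
#' @return List with elements `recording` (a [ga_recording()]) and `truth`.
#' @export
assemble_recording <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  fs <- config$fs
  n <- round(config$duration_s * fs)
  pad <- 0.5
  eeg <- numeric(n)
  gamma_sig <- numeric(n)
  planted_ies <- empty_segments()
  rhythms <- list(theta = list(), delta = list())
  with_seed(config$seed, {
    for (si in seq_along(config$stages)) {
      st <- config$stages[[si]]
      s_ext <- max(0, st$start_s - pad)
      e_ext <- min(config$duration_s, st$end_s + pad)
      n_ext <- round((e_ext - s_ext) * fs)
      idx <- (round(s_ext * fs) + 1):(round(s_ext * fs) + n_ext)
      frac_in <- (st$start_s - s_ext) * 2
      frac_out <- (e_ext - st$end_s) * 2
      env <- crossfade_envelope(n_ext, round(frac_in * fs),
                                round(frac_out * fs))
      ap <- st$aperiodic
      sig <- generate_aperiodic(ap[1], ap[2], ap[3], n_ext / fs, fs)
      for (bname in c("theta", "delta")) {
        b <- st[[bname]]
        if (!is.null(b) && b$amplitude > 0) {
          # extend the nominal trajectory linearly over the padded interval
          slope <- (b$f1 - b$f0) / (st$end_s - st$start_s)
          bx <- band_spec(b$amplitude, b$f0 + slope * (s_ext - st$start_s),
                          b$f0 + slope * (e_ext - st$start_s), b$sigma)
          sig <- sig + generate_oscillation(bx, n_ext / fs, fs)
          rhythms[[bname]][[length(rhythms[[bname]]) + 1]] <-
            list(start_s = st$start_s, end_s = st$end_s,
                 f0 = b$f0, f1 = b$f1, sigma = b$sigma)
        }
      }
      if (!is.null(st$gamma) && st$gamma$amplitude > 0) {
        g <- st$gamma
        osc <- generate_oscillation(
          band_spec(g$amplitude, g$center, g$center, g$sigma %||% 1),
          n_ext / fs, fs)
        period <- g$on_s + g$off_s
        tt <- s_ext + (seq_len(n_ext) - 1) / fs
        duty <- ((tt - st$start_s) %% period) < g$on_s & tt >= st$start_s &
          tt < st$end_s
        gseg <- osc * duty
        sig <- sig + gseg
        gamma_sig[idx] <- gamma_sig[idx] + gseg * env
      }
      eeg[idx] <- eeg[idx] + sig * env
      if (st$ies_fraction > 0) {
        planted_ies <- rbind(planted_ies,
                             plan_ies_segments(st$start_s, st$end_s,
                                               st$ies_fraction))
      }
    }
    planted_ies <- as_segments(planted_ies)
    # realize planted IES as near-flat traces (2% residual amplitude)
    for (i in seq_len(nrow(planted_ies))) {
      ii <- (floor(planted_ies[i, 1] * fs) + 1):
        min(n, round(planted_ies[i, 2] * fs))
      eeg[ii] <- eeg[ii] * 0.02
    }
    emg <- NULL
    if (!is.na(config$tau_lom) || !is.na(config$tau_rom)) {
      wn <- stats::rnorm(n)
      emg <- bandpass(wn, 20, min(200, fs / 2 - 1), fs)
      emg <- emg / rms(emg) * 30
      lom <- if (is.na(config$tau_lom)) 0 else config$tau_lom
      rom <- if (is.na(config$tau_rom)) config$duration_s else config$tau_rom
      ii <- (floor(lom * fs) + 1):min(n, round(rom * fs))
      emg[ii] <- emg[ii] * 0.05
    }
    rec <- ga_recording(eeg, fs = fs, emg = emg,
                        annotations = list(
                          tau_iso_start = config$tau_iso_start,
                          tau_iso_stop = config$tau_iso_stop,
                          tau_lom = config$tau_lom,
                          tau_rom = config$tau_rom))
    truth <- list(
      planted_ies = planted_ies,
      rhythms = rhythms,
      true_events = true_events_from_stages(config, planted_ies),
      true_gamma_area = {
        i0 <- floor(config$tau_iso_stop * fs) + 1
        sum(gamma_sig[i0:n]^2) / fs
      },
      emg_lom_rom = c(config$tau_lom, config$tau_rom))
    list(recording = rec, truth = truth)
  })
}

# Ground-truth event timestamps from the nominal stage boundaries, relative
# to tau_iso_start (NA when an event was not planted). The strong-IES time
# is derived from the planted segments with the same ratio/persistence
# definition used downstream, evaluated by exact interval arithmetic.
true_events_from_stages <- function(config, planted_ies) {
  t0 <- config$tau_iso_start
  stages <- config$stages
  has <- function(st, what) switch(what,
    theta = !is.null(st$theta) && st$theta$amplitude > 0,
    delta = !is.null(st$delta) && st$delta$amplitude > 0,
    gamma = !is.null(st$gamma) && st$gamma$amplitude > 0)
  ev <- list(tau_theta_decay = NA_real_, tau_delta_app = NA_real_,
             tau_theta_disp = NA_real_, tau_delta_disp = NA_real_,
             tau_ies1 = NA_real_, tau_s = NA_real_, tau_gamma = NA_real_)
  delta_seen <- FALSE; theta_prev <- FALSE
  for (st in stages) {
    at <- st$start_s
    if (is.na(ev$tau_theta_decay) && at >= t0 && has(st, "theta") &&
        st$theta$f1 < st$theta$f0)
      ev$tau_theta_decay <- at - t0
    if (is.na(ev$tau_delta_app) && at >= t0 && has(st, "delta")) {
      ev$tau_delta_app <- at - t0
      delta_seen <- TRUE
    }
    if (is.na(ev$tau_theta_disp) && at >= t0 && theta_prev &&
        !has(st, "theta"))
      ev$tau_theta_disp <- at - t0
    if (is.na(ev$tau_delta_disp) && delta_seen && !has(st, "delta") &&
        at >= t0 + (ev$tau_delta_app %||% 0))
      ev$tau_delta_disp <- at - t0
    if (is.na(ev$tau_gamma) && has(st, "gamma") && at >= config$tau_iso_stop)
      ev$tau_gamma <- at - t0
    theta_prev <- has(st, "theta")
  }
  if (nrow(planted_ies) > 0) {
    ev$tau_ies1 <- unname(planted_ies[1, 1]) - t0
    grid <- make_grid(config$duration_s, 20, 10)
    ratio <- vapply(grid$centers, function(ct)
      overlap_duration(planted_ies, ct - 10, ct + 10) / 20, numeric(1))
    ev$tau_s <- strong_onset_from_ratio(ratio, grid$centers, 0.25, 40, t0)
  }
  ev
}

# ---- bundled scenarios ------------------------------------------------------

#' Bundled "deep anesthesia" scenario
#'
#' 20 min at 500 Hz: awake baseline with a stable 8 Hz theta rhythm,
#' induction at 115 s, theta chirping 8 to 6 Hz over 2 min (-1 Hz/min) and
#' then holding at 6 Hz, delta (3 Hz) appearing then remaining alone, both
#' bands dampening, a strong burst-suppression stage (half the time in
#' planted IES), anesthetic off at 14 min, and a 60 Hz gamma-rebound burst
#' train during recovery. Movement is lost at 410 s and returns at 850 s.
#'
#' @param seed Integer seed.
#' @return A [scenario_config()].
#' @export
deep_scenario <- function(seed = 7) {
  ap <- c(a = 100, c = 1, p = 2)
  scenario_config(
    fs = 500, duration_s = 1200, tau_iso_start = 115, tau_iso_stop = 840,
    tau_lom = 410, tau_rom = 850, seed = seed,
    stages = list(
      stage_spec(0, 120, ap, theta = band_spec(14, 8, 8, 0.5)),
      stage_spec(120, 240, ap, theta = band_spec(14, 8, 6, 0.5)),
      stage_spec(240, 420, ap, theta = band_spec(14, 6, 6, 0.5),
                 delta = band_spec(18, 3, 3, 0.4)),
      stage_spec(420, 540, ap, delta = band_spec(18, 3, 3, 0.4)),
      stage_spec(540, 620, ap),
      stage_spec(620, 840, ap, ies_fraction = 0.5),
      stage_spec(840, 1200, ap,
                 gamma = list(amplitude = 10, center = 60, sigma = 1,
                              on_s = 2, off_s = 0.5),
                 emg_active = TRUE)))
}

#' Bundled "light anesthesia" scenario
#'
#' 15 min at 500 Hz with the same induction sequence as [deep_scenario()]
#' but no iso-electric suppression and no gamma rebound: delta dampens when
#' the anesthetic is switched off at 10 min and the animal resumes moving.
#'
#' @param seed Integer seed.
#' @return A [scenario_config()].
#' @export
light_scenario <- function(seed = 1) {
  ap <- c(a = 100, c = 1, p = 2)
  scenario_config(
    fs = 500, duration_s = 900, tau_iso_start = 115, tau_iso_stop = 600,
    tau_lom = 410, tau_rom = 610, seed = seed,
    stages = list(
      stage_spec(0, 120, ap, theta = band_spec(14, 8, 8, 0.5)),
      stage_spec(120, 240, ap, theta = band_spec(14, 8, 6, 0.5)),
      stage_spec(240, 420, ap, theta = band_spec(14, 6, 6, 0.5),
                 delta = band_spec(18, 3, 3, 0.4)),
      stage_spec(420, 600, ap, delta = band_spec(18, 3, 3, 0.4)),
      stage_spec(600, 900, ap, theta = band_spec(14, 8, 8, 0.5))))
}

#' Read a scenario configuration from YAML or JSON
#'
#' The file mirrors the [scenario_config()] fields; each stage lists its
#' interval, `aperiodic: [a, c, p]` and optional `theta`/`delta`
#' (`[amplitude, f0, f1, sigma]`), `ies_fraction` and `gamma` blocks.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` scenario file.
#' @export
read_scenario <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  as_band <- function(v) if (is.null(v)) NULL else
    band_spec(v[[1]], v[[2]], if (length(v) >= 3) v[[3]] else v[[2]],
              if (length(v) >= 4) v[[4]] else 0)
  stages <- lapply(raw$stages, function(s)
    stage_spec(s$interval[[1]], s$interval[[2]],
               aperiodic = unlist(s$aperiodic),
               theta = as_band(s$theta), delta = as_band(s$delta),
               ies_fraction = s$ies_fraction %||% 0,
               gamma = s$gamma))
  scenario_config(fs = raw$fs, duration_s = raw$duration_s,
                  tau_iso_start = raw$tau_iso_start,
                  tau_iso_stop = raw$tau_iso_stop, stages = stages,
                  seed = raw$seed %||% 1,
                  tau_lom = raw$tau_lom %||% NA,
                  tau_rom = raw$tau_rom %||% NA)
}

#' Serialize ground truth to JSON
#' @param truth The `truth` element returned by [assemble_recording()].
#' @param path Output path.
#' @export
write_truth_json <- function(truth, path) {
  out <- truth
  out$planted_ies <- unname(apply(truth$planted_ies, 1, function(r)
    c(r[1], r[2]), simplify = FALSE))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
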