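# Synthetic generator: determinism, spectral fidelity, planted ground truth.

test_that("aperiodic generator is deterministic and validates arguments", {
  a <- generate_aperiodic(1, 1, 2, 10, 250, seed = 3)
  b <- generate_aperiodic(1, 1, 2, 10, 250, seed = 3)
  expect_identical(a, b)
  expect_false(identical(a, generate_aperiodic(1, 1, 2, 10, 250, seed = 4)))
  expect_error(generate_aperiodic(1, 1, 2, 0, 500), class =
                 "anesmap_invalid_argument")
  expect_error(generate_aperiodic(-1, 1, 2, 10, 500), class =
                 "anesmap_invalid_argument")
  expect_lt(abs(mean(a)), 0.05 * sd(a))
})

test_that("aperiodic PSD follows a/(c+f^p): flat at p = 0, slope -p else", {
  # p = 0 forces a flat spectrum
  x <- generate_aperiodic(1, 1, 0, 60, 500, seed = 7)
  w <- welch_psd(x, 500)
  keep <- w$freq >= 1 & w$freq <= 15
  sl <- coef(lm(log(w$psd[keep]) ~ log(w$freq[keep])))[2]
  expect_lt(abs(sl), 0.15)
  # steep spectra: log-log slope within 0.3 of -p for c << 1
  for (p in c(1, 2)) {
    x <- generate_aperiodic(1, 0.01, p, 300, 500, seed = p)
    w <- welch_psd(x, 500)
    keep <- w$freq >= 1 & w$freq <= 15
    sl <- coef(lm(log(w$psd[keep]) ~ log(w$freq[keep])))[2]
    expect_lt(abs(sl + p), 0.3)
  }
})

test_that("oscillation generator hits its frequency and rejects bad bands", {
  x <- generate_oscillation(band_spec(2, 8), 60, 500, seed = 1)
  expect_equal(fft_peak_freq(x, 500), 8, tolerance = 0.2 / 8)
  w <- welch_psd(x, 500)
  expect_lt(abs(w$freq[which.max(w$psd)] - 8), 0.21)
  expect_identical(generate_oscillation(band_spec(0, 8), 1, 500), numeric(500))
  expect_error(generate_oscillation(band_spec(1, 300), 1, 500, 1),
               class = "anesmap_invalid_argument")
  expect_error(generate_oscillation(band_spec(1, -2), 1, 500, 1),
               class = "anesmap_invalid_argument")
})

test_that("scenario configs enforce tiling and protocol invariants", {
  ap <- c(1, 1, 2)
  expect_error(scenario_config(500, 100, 10, 50, list(
    stage_spec(0, 40, ap), stage_spec(50, 100, ap))),
    class = "anesmap_invalid_argument")   # gap
  expect_error(scenario_config(500, 100, 60, 50, list(stage_spec(0, 100, ap))),
               class = "anesmap_invalid_argument")  # iso_stop < iso_start
  expect_error(scenario_config(
    100, 10, 0, 5, list(stage_spec(0, 10, ap, theta = band_spec(1, 60)))),
    class = "anesmap_invalid_argument")   # fs too low for planted band
})

test_that("assembled recordings are seed-deterministic with consistent truth", {
  s1 <- assemble_recording(light_scenario(seed = 5))
  s2 <- assemble_recording(light_scenario(seed = 5))
  expect_identical(s1$recording$eeg, s2$recording$eeg)
  expect_identical(s1$recording$emg, s2$recording$emg)
  expect_identical(s1$truth, s2$truth)
  # light scenario: nothing suppressive or gamma planted
  expect_equal(nrow(s1$truth$planted_ies), 0)
  expect_true(is.na(s1$truth$true_events$tau_s))
  expect_true(is.na(s1$truth$true_events$tau_gamma))
  expect_equal(s1$truth$true_gamma_area, 0)
})

test_that("planted IES segments hit the requested fraction and spacing", {
  sim <- deep_sim()
  seg <- sim$truth$planted_ies
  st <- deep_scenario()$stages[[6]]
  expect_true(all(seg[, 1] >= st$start_s & seg[, 2] <= st$end_s))
  target <- st$ies_fraction * (st$end_s - st$start_s)
  realized <- sum(seg[, 2] - seg[, 1])
  expect_lt(abs(realized - target) / target, 0.05)
  expect_true(all(seg[, 2] - seg[, 1] >= 1))        # every segment >= 1 s
  if (nrow(seg) > 1)
    expect_true(all(seg[-1, 1] - seg[-nrow(seg), 2] > 0.5))  # unmergeable gaps
})

test_that("deep-scenario ground truth carries the full ordered event chain", {
  ev <- deep_sim()$truth$true_events
  expect_true(all(!is.na(unlist(ev))))
  chain <- c(ev$tau_theta_decay, ev$tau_delta_app, ev$tau_theta_disp,
             ev$tau_delta_disp, ev$tau_s, ev$tau_gamma)
  expect_true(all(diff(chain) > 0))
  expect_true(ev$tau_ies1 <= ev$tau_s)
})

test_that("EMG is active before LOM, flat between LOM and ROM", {
  rec <- light_sim()$recording
  fs <- rec$fs
  seg_rms <- function(t1, t2)
    sqrt(mean(rec$emg[(t1 * fs + 1):(t2 * fs)]^2))
  expect_gt(seg_rms(100, 300) / seg_rms(450, 550), 10)
  expect_gt(seg_rms(700, 880) / seg_rms(450, 550), 10)
})

test_that("scenario files round-trip through YAML", {
  cfg <- light_scenario(seed = 2)
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    fs = cfg$fs, duration_s = cfg$duration_s,
    tau_iso_start = cfg$tau_iso_start, tau_iso_stop = cfg$tau_iso_stop,
    tau_lom = cfg$tau_lom, tau_rom = cfg$tau_rom, seed = cfg$seed,
    stages = lapply(cfg$stages, function(s) {
      out <- list(interval = c(s$start_s, s$end_s),
                  aperiodic = as.list(s$aperiodic),
                  ies_fraction = s$ies_fraction)
      for (b in c("theta", "delta"))
        if (!is.null(s[[b]]))
          out[[b]] <- list(s[[b]]$amplitude, s[[b]]$f0, s[[b]]$f1,
                           s[[b]]$sigma)
      out
    })), path)
  cfg2 <- read_scenario(path)
  r1 <- assemble_recording(cfg)
  r2 <- assemble_recording(cfg2)
  expect_identical(r1$recording$eeg, r2$recording$eeg)
})
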