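# Recording IO, artifact masking, filtering, RMS, window grids.

test_that("EDF round-trips EEG and EMG within 16-bit quantization", {
  sim <- assemble_recording(scenario_config(
    fs = 250, duration_s = 20, tau_iso_start = 5, tau_iso_stop = 15,
    tau_lom = 8, tau_rom = 16, seed = 2,
    stages = list(stage_spec(0, 20, c(50, 1, 2),
                             theta = band_spec(10, 8)))))
  rec <- sim$recording
  path <- tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_recording(path)
  expect_equal(back$fs, rec$fs)
  q <- diff(range(rec$eeg)) / 65535
  expect_lt(max(abs(back$eeg - rec$eeg)), 1.5 * q)
  expect_lt(max(abs(back$emg - rec$emg)), 1.5 * diff(range(rec$emg)) / 65535)
})

test_that("columnar text round-trips and infers the sampling rate", {
  rec <- ga_recording(sin(2 * pi * 3 * (0:999) / 100), fs = 100)
  path <- tempfile(fileext = ".txt")
  write_recording_text(rec, path)
  back <- read_recording(path, format = "text")
  expect_equal(back$fs, 100)
  expect_equal(back$eeg, rec$eeg, tolerance = 1e-12)
})

test_that("irregular time steps are rejected with the offending row", {
  path <- tempfile(fileext = ".txt")
  t <- c(0, 0.01, 0.02, 0.05, 0.06)
  writeLines(paste(t, rnorm(5)), path)
  expect_error(read_recording(path, format = "text"), "row 4")
})

test_that("annotation sidecar JSON is attached to the recording", {
  rec <- ga_recording(rnorm(1000), fs = 100)
  path <- tempfile(fileext = ".txt")
  write_recording_text(rec, path)
  ann <- tempfile(fileext = ".json")
  writeLines('{"tau_iso_start": 2, "tau_iso_stop": 8, "tau_lom": null}', ann)
  back <- read_recording(path, annotations = ann)
  expect_equal(back$annotations$tau_iso_start, 2)
  expect_true(is.na(back$annotations$tau_lom))
})

test_that("flat-line dropouts are masked exactly, clean traces untouched", {
  fs <- 100
  x <- sin(2 * pi * 2 * (0:(20 * fs - 1)) / fs) * 5
  x[501:1000] <- 0                                  # 5 s dropout
  rec <- mask_artifacts(ga_recording(x, fs))
  # brute-force scan for constant runs >= 0.5 s
  expected <- rep(FALSE, length(x))
  expected[501:1000] <- TRUE
  expect_identical(rec$mask, expected)
  clean <- mask_artifacts(ga_recording(sin(1:1000) + 2, fs))
  expect_false(any(clean$mask))
})

test_that("hysteresis masks the whole excursion touching the high threshold", {
  fs <- 100
  x <- sin(2 * pi * 1 * (0:(10 * fs - 1)) / fs) * 0.05   # below low threshold
  spike <- exp(-(0:(2 * fs)) / 40) * 2000   # 2000 -> ~0 decay over 2 s
  x[301:(301 + 2 * fs)] <- spike
  rec <- mask_artifacts(ga_recording(x, fs), low_thr = 0.08, high_thr = 1200)
  # flood-fill oracle: connected |x| > 0.08 region that contains |x| >= 1200
  above <- abs(x) > 0.08
  reg <- rle(above)
  ends <- cumsum(reg$lengths); starts <- ends - reg$lengths + 1
  expected <- rep(FALSE, length(x))
  for (k in which(reg$values))
    if (any(abs(x[starts[k]:ends[k]]) >= 1200))
      expected[starts[k]:ends[k]] <- TRUE
  expect_identical(rec$mask, expected)
  expect_true(any(rec$mask))
  # the decaying tail below 1200 but above 0.08 is included
  expect_true(rec$mask[301 + fs])
})

test_that("bandpass preserves in-band sinusoids in phase and rejects out-of-band", {
  fs <- 500
  t <- (0:(10 * fs - 1)) / fs
  x <- sin(2 * pi * 8 * t)
  y <- bandpass(x, 5, 10, fs)
  core <- (2 * fs):(8 * fs)               # avoid edge transients
  amp <- sqrt(2 * mean(y[core]^2))
  expect_gt(amp, 0.85)
  # cross-correlation lag oracle: zero-phase filter => max correlation at 0
  lags <- -5:5
  cc <- vapply(lags, function(l)
    cor(x[core], y[core + l]), numeric(1))
  expect_equal(lags[which.max(cc)], 0)
  y2 <- bandpass(x, 2.5, 4.5, fs)
  expect_lt(sqrt(mean(y2[core]^2)) / sqrt(mean(x^2)), 0.2)
  expect_identical(bandpass(numeric(100) , 5, 10, fs), numeric(100))
  expect_error(bandpass(x, 10, 5, fs), class = "anesmap_invalid_argument")
})

test_that("repeated filtering preserves a center-frequency sinusoid", {
  fs <- 500
  f0 <- sqrt(5 * 10)                      # geometric band center, unity gain
  x <- sin(2 * pi * f0 * (0:(20 * fs - 1)) / fs)
  y <- bandpass(x, 5, 10, fs)
  y2 <- bandpass(y, 5, 10, fs)
  core <- (5 * fs):(15 * fs)
  expect_lt(sqrt(mean((y2 - y)[core]^2)) / sqrt(mean(y[core]^2)), 0.01)
  # broadband input: the second pass only reshapes the wide order-1 skirts
  z <- bandpass(rnorm(10 * fs), 5, 10, fs)
  expect_gt(cor(z, bandpass(z, 5, 10, fs)), 0.9)
})

test_that("rms matches closed forms and respects the mask", {
  expect_equal(rms(rep(-3, 100)), 3)
  t <- (0:49999) / 500
  expect_equal(rms(sin(2 * pi * 5 * t)), 1 / sqrt(2), tolerance = 1e-3)
  expect_equal(rms(c(3, 4)), sqrt(12.5))
  expect_equal(rms(c(3, 4, 100), mask = c(FALSE, FALSE, TRUE)), sqrt(12.5))
  expect_error(rms(c(1, 2), mask = c(TRUE, TRUE)),
               class = "anesmap_degenerate_input")
})

test_that("window grids enumerate centers per the width/overlap contract", {
  g <- make_grid(100, 20, 10)
  expect_equal(g$centers, seq(10, 90, by = 10))
  expect_equal(make_grid(60, 60, 30)$centers, 30)
  expect_error(make_grid(10, 20, 10), class = "anesmap_invalid_argument")
  expect_error(make_grid(100, 20, 20), class = "anesmap_invalid_argument")
  # coverage: consecutive windows tile [0, last end] exactly
  g2 <- make_grid(95, 10, 5)
  expect_true(all(abs(diff(g2$centers) - 5) < 1e-12))
  expect_lte(g2$centers[length(g2$centers)] + 5, 95)
})
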