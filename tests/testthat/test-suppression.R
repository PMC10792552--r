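# Suppression segmentation, ratios, timestamps, threshold sweep.

test_that("detector equals the brute-force run-length oracle on random signals", {
  set.seed(42)
  for (i in 1:100) {
    fs <- 100
    n <- 10 * fs
    # block-wise amplitude so that multi-second quiet runs actually occur
    blocks <- rep(sample(c(0.05, 0.5, 2), 10, replace = TRUE), each = fs)
    x <- blocks * sin(2 * pi * sample(2:8, 1) * (1:n) / fs) +
      rnorm(n, sd = 0.01)
    thr <- runif(1, 0.1, 1)
    got <- detect_suppressions(x, fs, thr)
    want <- brute_force_suppressions(x, fs, thr)
    expect_equal(unname(got), unname(want))
  }
})

test_that("two long quiet runs bridged by a short burst merge into one", {
  fs <- 200
  seg <- function(dur, amp, f = 10)
    amp * sin(2 * pi * f * seq(0, dur, length.out = dur * fs))
  x <- c(seg(3, 5), seg(1.2, 0.1), seg(0.3, 5), seg(1.2, 0.1), seg(3, 5))
  got <- detect_suppressions(x, fs, threshold = 1)
  expect_equal(nrow(got), 1)
  expect_equal(unname(got[1, 2] - got[1, 1]), 2.7, tolerance = 0.05)
})

test_that("an ongoing oscillation above threshold yields no suppressions", {
  fs <- 500
  x <- 2 * sin(2 * pi * 6 * (0:(20 * fs - 1)) / fs)
  expect_equal(nrow(detect_suppressions(x, fs, threshold = 1)), 0)
  expect_error(detect_suppressions(numeric(0), fs, 1),
               class = "anesmap_degenerate_input")
})

test_that("masked samples never count as suppression", {
  fs <- 100
  x <- c(rep(5, 5 * fs), rep(0, 5 * fs), rep(5, 5 * fs))
  mask <- rep(FALSE, length(x))
  mask[501:1000] <- TRUE
  expect_equal(nrow(detect_suppressions(x, fs, 1, mask = mask)), 0)
  expect_equal(nrow(detect_suppressions(x, fs, 1)), 1)
})

test_that("detected IES on the deep scenario recovers the planted segments", {
  sim <- deep_sim()
  res <- deep_run()
  expect_gte(segments_jaccard_test(res$ies, sim$truth$planted_ies), 0.9)
  planted <- sum(sim$truth$planted_ies[, 2] - sim$truth$planted_ies[, 1])
  expect_lte(abs(res$ies_sum$delta_ies - planted) / planted, 0.05)
  # light scenario: rhythms well above threshold, nothing detected
  expect_equal(nrow(light_run()$ies), 0)
})

test_that("band suppressions cover band-absent epochs when in-band noise is low", {
  # rhythms well above a faint broadband floor: theta planted for the first
  # 300 s, absent afterwards while delta persists
  fs <- 250
  bg <- generate_aperiodic(2, 1, 2, 600, fs, seed = 4)
  th <- generate_oscillation(band_spec(12, 7), 600, fs, seed = 5)
  de <- generate_oscillation(band_spec(12, 3), 600, fs, seed = 6)
  th[(300 * fs):(600 * fs - 1) + 1] <- 0
  rec <- ga_recording(bg + th + de, fs)
  ies <- detect_ies(rec)
  ths <- detect_band_suppressions(rec, "theta", ies)
  expect_gt(oracle_overlap(ths, 305, 600) / 295, 0.85)
  expect_lt(oracle_overlap(ths, 0, 295), 10)
  # a pure delta oscillation with no theta at all: thetaS covers everything
  rec2 <- ga_recording(20 * sin(2 * pi * 3 * (0:(240 * fs - 1)) / fs), fs)
  ths2 <- detect_band_suppressions(rec2, "theta", detect_ies(rec2))
  expect_gt(oracle_overlap(ths2, 5, 235) / 230, 0.95)
  expect_error(detect_band_suppressions(rec2, "beta", detect_ies(rec2)))
})

test_that("band suppressions never intersect IES on the deep scenario", {
  res <- deep_run()
  # no theta suppression while the theta rhythm is strong
  expect_lt(oracle_overlap(res$theta_supp, 0, 110), 10)
  for (seg in list(res$theta_supp, res$delta_supp)) {
    for (i in seq_len(nrow(seg)))
      expect_equal(oracle_overlap(res$ies, seg[i, 1], seg[i, 2]), 0)
  }
})

test_that("suppression ratios equal interval intersection over window width", {
  seg <- rbind(c(10, 40), c(100, 101.5))
  grid <- make_grid(200, 20, 10)
  r <- suppression_ratios(seg, grid)
  expect_true(all(r >= 0 & r <= 1))
  expect_equal(r[grid$centers == 20], 1)          # fully inside [10, 30]
  expect_equal(r[grid$centers == 40], 0.5)        # half covered [30, 50]
  expect_equal(r[grid$centers == 70], 0)          # empty
  expect_equal(r[grid$centers == 100], 1.5 / 20)
})

test_that("ies_summary reports first IES, cumulative duration, strong onset", {
  fs <- 250
  dur <- 300
  x <- 10 * sin(2 * pi * 7 * (0:(dur * fs - 1)) / fs)
  x[(100 * fs):(130 * fs)] <- 0.01 * x[(100 * fs):(130 * fs)]
  rec <- ga_recording(x, fs, annotations = list(tau_iso_start = 50,
                                                tau_iso_stop = 250))
  ies <- detect_ies(rec)
  s <- ies_summary(ies, rec)
  expect_equal(s$tau_ies1, 50, tolerance = 0.05)
  expect_equal(s$delta_ies, 30, tolerance = 0.5)
  # one 30 s segment cannot sustain IESSR > 0.25 for 40 s
  expect_true(is.na(s$tau_s))
  # no IES at all
  rec2 <- ga_recording(10 * sin(2 * pi * 7 * (0:(60 * fs - 1)) / fs), fs,
                       annotations = list(tau_iso_start = 10))
  s2 <- ies_summary(detect_ies(rec2), rec2)
  expect_true(is.na(s2$tau_ies1))
  expect_equal(s2$delta_ies, 0)
  expect_true(is.na(s2$tau_s))
})

test_that("strong-IES onset lands within one ratio step of the planted onset", {
  sim <- deep_sim()
  res <- deep_run()
  expect_lte(abs(res$ies_sum$tau_s - sim$truth$true_events$tau_s), 10)
})

test_that("threshold sweep is monotone with a plateau at the planted duration", {
  rec <- deep_sim()$recording
  sw <- sweep_ies_threshold(rec, seq(0.1, 1.3, by = 0.2))
  expect_true(all(diff(sw$total_ies_s) >= 0))
  planted <- sum(deep_sim()$truth$planted_ies[, 2] -
                   deep_sim()$truth$planted_ies[, 1])
  # around r = 0.7 the detected duration sits at the planted duration
  # (very high r eventually swallows the quiet pre-IES background)
  mid <- sw$total_ies_s[sw$r_ies > 0.45 & sw$r_ies < 0.75]
  expect_true(all(abs(mid - planted) / planted < 0.1))
})
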