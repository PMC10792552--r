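# Welch PSD, IRASA, aperiodic and Gaussian fits, tracking, theta decay,
# power ratios and prominence times.

test_that("welch_psd peaks at the planted frequency and conserves power", {
  fs <- 500
  x <- sin(2 * pi * 8 * (0:(60 * fs - 1)) / fs)
  w <- welch_psd(x, fs)
  expect_equal(w$freq[which.max(w$psd)], 8)
  expect_equal(min(diff(w$freq)), 0.2, tolerance = 1e-9)
  # white noise: flat within sampling error; in-band integral matches the
  # band's share of the total variance (Parseval)
  set.seed(1)
  n <- rnorm(120 * fs)
  wn <- welch_psd(n, fs, fmin = 0.2, fmax = 15)
  band_power <- sum(wn$psd) * 0.2
  expect_equal(band_power, var(n) * (15 / 250), tolerance = 0.1)
  expect_lt(sd(log(wn$psd)), 0.5)
  expect_true(all(welch_psd(numeric(10 * fs), fs)$psd == 0))
  expect_error(welch_psd(rnorm(100), fs), class = "anesmap_invalid_argument")
})

test_that("IRASA leaves the fractal part intact and suppresses oscillations", {
  fs <- 500
  x <- generate_aperiodic(1, 0.1, 2, 300, fs, seed = 11)
  fr <- irasa_aperiodic(x, fs)
  tru <- 1 / (0.1 + fr$freq^2)
  mid <- fr$freq >= 1 & fr$freq <= 10
  expect_true(all(abs(fr$psd[mid] / tru[mid] - 1) < 0.2))
  # strong 8 Hz line: median PSD at 8 Hz far below the raw peak
  y <- x + generate_oscillation(band_spec(1.5, 8, 8, 0.5), 300, fs, seed = 2)
  raw <- welch_psd(y, fs)
  fr2 <- irasa_aperiodic(y, fs)
  at8 <- which.min(abs(raw$freq - 8))
  expect_lt(fr2$psd[at8] / raw$psd[at8], 0.15)
  expect_true(all(irasa_aperiodic(numeric(60 * fs), fs)$psd == 0))
})

test_that("aperiodic fit recovers exact curves to 1% (noiseless input)", {
  freq <- seq(0.2, 15, by = 0.2)
  f1 <- fit_aperiodic(freq, 2 / (0.5 + freq^2))
  expect_true(f1$ok)
  expect_equal(f1$a, 2, tolerance = 0.01)
  expect_equal(f1$c, 0.5, tolerance = 0.05)
  expect_equal(f1$p, 2, tolerance = 0.01)
  f2 <- fit_aperiodic(freq, 1 / freq)        # c = 0, p = 1
  expect_equal(f2$p, 1, tolerance = 0.01)
  expect_lt(f2$c, 0.05)
  f3 <- fit_aperiodic(freq, rep(3, length(freq)))
  expect_lt(f3$p, 0.05)                      # flat spectrum -> p ~ 0
  expect_false(fit_aperiodic(freq, rep(0, length(freq)))$ok)
})

test_that("decomposition is consistent: fit + clipped residual >= raw - rss", {
  fs <- 500
  x <- generate_aperiodic(1, 0.5, 2, 120, fs, seed = 3) +
    generate_oscillation(band_spec(1, 8, 8, 0.5), 120, fs, seed = 4)
  raw <- welch_psd(x, fs)
  fr <- irasa_aperiodic(x, fs)
  ap <- fit_aperiodic(fr$freq, fr$psd)
  recon <- ap$a / (ap$c + raw$freq^ap$p) +
    pmax(raw$psd - ap$a / (ap$c + raw$freq^ap$p), 0)
  expect_true(all(recon >= raw$psd - 1e-9))
})

test_that("Gaussian components obey the pruning rules (construction tests)", {
  freq <- seq(0.2, 15, by = 0.2)
  base <- 1 / (0.5 + freq^1.5)
  ap <- fit_aperiodic(freq, base)
  gauss <- function(b, f0, s) b * exp(-(freq - f0)^2 / (2 * s^2))
  # healthy component detected at its center
  c1 <- fit_oscillatory(freq, base + gauss(0.5, 8, 0.5), ap)
  expect_equal(nrow(c1), 1)
  expect_equal(c1$band, "theta")
  expect_lt(abs(c1$f - 8), 0.3)
  # sigma = 0.1 (too narrow) and sigma = 3 (too wide) are pruned
  expect_equal(nrow(fit_oscillatory(freq, base + gauss(0.5, 8, 0.1), ap)), 0)
  expect_equal(nrow(fit_oscillatory(freq, base + gauss(0.5, 8, 3), ap)), 0)
  # amplitude below the residual-std threshold is pruned: two peaks where
  # the large one dominates the std so the tiny one fails b > std(resid)
  two <- base + gauss(1, 8, 0.5) + gauss(0.05, 3, 0.5)
  c2 <- fit_oscillatory(freq, two, ap)
  expect_true(all(c2$band == "theta"))
})

test_that("band selection takes the largest area, ties break toward the median", {
  freq <- seq(0.2, 15, by = 0.2)
  base <- 1 / (0.5 + freq^1.5)
  ap <- fit_aperiodic(freq, base)
  gauss <- function(b, f0, s) b * exp(-(freq - f0)^2 / (2 * s^2))
  # area rule: 9 Hz has twice the area of 6 Hz -> 9 Hz selected
  c1 <- fit_oscillatory(freq, base + gauss(0.5, 6, 0.5) +
                          gauss(0.5, 9, 1.0), ap)
  th <- c1[c1$band == "theta", ]
  expect_equal(nrow(th), 1)
  expect_gt(th$f, 8)
  # one component per band at most
  c2 <- fit_oscillatory(freq, base + gauss(0.6, 3, 0.5) +
                          gauss(0.6, 8, 0.5), ap)
  expect_setequal(c2$band, c("theta", "delta"))
})

test_that("rhythm tracking interpolates runs and drops isolated detections", {
  fr <- data.frame(center_s = seq(30, 240, by = 30),
                   theta_f = c(8, 7, NA, NA, 6, NA, NA, 5),
                   theta_sigma = c(0.5, 0.7, NA, NA, 0.5, NA, NA, 0.5))
  fr$delta_f <- NA_real_; fr$delta_sigma <- NA_real_
  tr <- track_rhythms(fr, "theta")
  # detections at 30 & 60 form a run; 150 and 240 are isolated -> dropped
  expect_equal(nrow(tr$valid_intervals), 1)
  expect_equal(unname(tr$valid_intervals[1, ]), c(30, 60))
  expect_equal(tr$f_of_t(45), 7.5)              # straight-line interpolation
  expect_equal(tr$f_of_t(30), 8)                # exact at frame centers
  expect_true(is.na(tr$f_of_t(150)))
  expect_true(is.na(tr$f_of_t(100)))
  # up - low = 2 sigma wherever defined
  expect_equal(tr$up(45) - tr$low(45), 2 * tr$sigma_of_t(45))
})

test_that("theta-decay onset and slope follow the Eq-style definition", {
  centers <- seq(30, 900, by = 30)
  mkframes <- function(f) data.frame(center_s = centers, theta_f = f,
                                     theta_sigma = 0.5,
                                     delta_f = NA_real_,
                                     delta_sigma = NA_real_)
  ann <- list(tau_iso_start = 115)
  # decay starting ~3 min after induction (at 300 s), -1 Hz/min for 4 min
  f <- ifelse(centers < 300, 8,
              pmax(8 - (centers - 300) / 60, 4))
  d <- theta_decay(track_rhythms(mkframes(f), "theta"), mkframes(f), ann)
  expect_lte(abs(d$tau_theta_decay - 185), 30)
  expect_equal(d$slope_hz_per_min, -1, tolerance = 0.15)
  # constant frequency: the strict inequality never holds for 5 min
  d2 <- theta_decay(track_rhythms(mkframes(rep(8, length(centers))), "theta"),
                    mkframes(rep(8, length(centers))), ann)
  expect_true(is.na(d2$tau_theta_decay))
  expect_true(is.na(d2$slope_hz_per_min))
})

test_that("deep-scenario slope recovers the planted -1 Hz/min theta chirp", {
  res <- deep_run()
  expect_equal(res$decay$slope_hz_per_min, -1, tolerance = 0.2)
  expect_lte(abs(res$decay$tau_theta_decay -
                   deep_sim()$truth$true_events$tau_theta_decay), 30)
})

test_that("power ratios isolate pure band sinusoids", {
  fs <- 500
  t <- (0:(120 * fs - 1)) / fs
  r8 <- power_ratios(ga_recording(sin(2 * pi * 8 * t), fs))
  expect_true(all(r8$p_theta > 0.9))
  expect_true(all(r8$p_delta < 0.05))
  # the order-1 delta filter passes only ~77% of a 3 Hz tone (3 Hz sits off
  # the 2.5-4.5 Hz geometric center), so the ratio lands near 0.8, not 1
  r3 <- power_ratios(ga_recording(sin(2 * pi * 3 * t), fs))
  expect_true(all(r3$p_delta > 0.75))
  expect_true(all(r3$p_theta < 0.05))
  rz <- power_ratios(ga_recording(numeric(60 * fs), fs))
  expect_true(all(is.na(rz$p_theta)))
})

test_that("prominence needs a full sustained minute", {
  ann <- list(tau_iso_start = 0)
  centers <- seq(10, 590, by = 20)
  # delta exceeds the threshold for only 40 s -> no appearance
  pd <- rep(0.05, length(centers))
  pd[centers > 200 & centers <= 240] <- 0.5
  r <- data.frame(center_s = centers, p_theta = 0.5, p_delta = pd)
  b <- band_prominence_times(r, ann)
  expect_true(is.na(b$tau_delta_app))
  expect_true(is.na(b$tau_delta_disp))
  # sustained delta: appearance at its first window, dampening afterwards
  pd2 <- ifelse(centers > 200 & centers <= 400, 0.5, 0.05)
  b2 <- band_prominence_times(data.frame(center_s = centers, p_theta = 0.5,
                                         p_delta = pd2), ann)
  expect_equal(b2$tau_delta_app, 210)
  expect_equal(b2$tau_delta_disp, 410)
  expect_true(is.na(b2$tau_theta_disp))
})
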