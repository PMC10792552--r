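# Independent brute-force oracles and shared (cached) scenario fixtures.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

deep_sim <- function(seed = 7)
  cached(paste0("deep_sim_", seed), assemble_recording(deep_scenario(seed)))

deep_run <- function(seed = 7)
  cached(paste0("deep_run_", seed), run_pipeline(deep_sim(seed)$recording))

light_sim <- function(seed = 1)
  cached(paste0("light_sim_", seed), assemble_recording(light_scenario(seed)))

light_run <- function(seed = 1)
  cached(paste0("light_run_", seed), run_pipeline(light_sim(seed)$recording))

# O(n) sample-by-sample suppression scanner: walk the signal, collect
# below-threshold runs >= min_dur, then merge pairs separated by < gap.
# Written independently of the package's rle/interval implementation.
brute_force_suppressions <- function(x, fs, threshold, min_dur_s = 1,
                                     merge_gap_s = 0.5) {
  runs <- list()
  start <- NA
  for (i in seq_along(x)) {
    if (abs(x[i]) < threshold) {
      if (is.na(start)) start <- i
    } else if (!is.na(start)) {
      runs[[length(runs) + 1]] <- c(start, i - 1)
      start <- NA
    }
  }
  if (!is.na(start)) runs[[length(runs) + 1]] <- c(start, length(x))
  segs <- list()
  for (r in runs) {
    s <- (r[1] - 1) / fs; e <- r[2] / fs
    if (e - s >= min_dur_s - 1e-9) segs[[length(segs) + 1]] <- c(s, e)
  }
  if (length(segs) == 0)
    return(matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  out <- list(segs[[1]])
  for (k in seq_along(segs)[-1]) {
    last <- out[[length(out)]]
    if (segs[[k]][1] - last[2] < merge_gap_s)
      out[[length(out)]][2] <- segs[[k]][2]
    else out[[length(out) + 1]] <- segs[[k]]
  }
  m <- do.call(rbind, out)
  dimnames(m) <- list(NULL, c("start", "end"))
  m
}

# Total overlap between a segment matrix and [a, b), by direct summation.
oracle_overlap <- function(seg, a, b) {
  tot <- 0
  for (i in seq_len(nrow(seg)))
    tot <- tot + max(0, min(seg[i, 2], b) - max(seg[i, 1], a))
  tot
}

# Dominant-frequency oracle: location of the maximum of a plain
# periodogram (no Welch averaging).
fft_peak_freq <- function(x, fs) {
  n <- length(x)
  p <- Mod(stats::fft(x))[2:(n %/% 2)]
  f <- (1:(n %/% 2 - 1)) * fs / n
  f[which.max(p)]
}

# Duration-weighted Jaccard between two disjoint segment lists, via the
# overlap oracle (independent of the package's interval code).
segments_jaccard_test <- function(a, b) {
  inter <- sum(vapply(seq_len(nrow(a)), function(i)
    oracle_overlap(b, a[i, 1], a[i, 2]), numeric(1)))
  uni <- sum(a[, 2] - a[, 1]) + sum(b[, 2] - b[, 1]) - inter
  inter / uni
}

# Rhythm amplitude used in the aperiodic-recovery study: peak spectral
# density ~ratio times the aperiodic PSD at the rhythm frequency.
rhythm_amp_for <- function(a, c_, p, f0, ratio = 40)
  sqrt(ratio * a / (c_ + f0^p) / 0.8)
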