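# Internal helpers shared across modules: scoped RNG, interval arithmetic on
# half-open [start, end) segments (numeric two-column matrices, seconds), and
# argument checks.

#' @keywords internal
stop_invalid <- function(...) {
  stop(structure(class = c("anesmap_invalid_argument", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' @keywords internal
stop_degenerate <- function(...) {
  stop(structure(class = c("anesmap_degenerate_input", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Evaluate `expr` with a temporary RNG seed, restoring the caller's RNG state.
# A NULL seed leaves the global stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_invalid("seed must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# ---- segment (interval) arithmetic -----------------------------------------
# Segments are matrices with columns start, end; half-open [start, end);
# rows sorted by start and pairwise disjoint.

empty_segments <- function() {
  matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
}

as_segments <- function(x) {
  if (is.null(x) || length(x) == 0) return(empty_segments())
  m <- matrix(as.numeric(x), ncol = 2)
  colnames(m) <- c("start", "end")
  m <- m[m[, 2] > m[, 1], , drop = FALSE]
  m[order(m[, 1]), , drop = FALSE]
}

segment_durations <- function(seg) {
  if (nrow(seg) == 0) return(numeric(0))
  seg[, 2] - seg[, 1]
}

total_duration <- function(seg) sum(segment_durations(seg))

# Merge segments separated by a gap smaller than `gap` (gap = 0 merges only
# touching/overlapping segments).
merge_segments <- function(seg, gap = 0) {
  seg <- as_segments(seg)
  if (nrow(seg) <= 1) return(seg)
  out <- seg[1, , drop = FALSE]
  for (i in 2:nrow(seg)) {
    if (seg[i, 1] - out[nrow(out), 2] < gap ||
        seg[i, 1] <= out[nrow(out), 2]) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], seg[i, 2])
    } else {
      out <- rbind(out, seg[i, , drop = FALSE])
    }
  }
  out
}

# Interval difference a \ b.
setdiff_segments <- function(a, b) {
  a <- as_segments(a); b <- as_segments(b)
  if (nrow(a) == 0 || nrow(b) == 0) return(a)
  pieces <- list()
  for (i in seq_len(nrow(a))) {
    cur <- a[i, , drop = FALSE]
    for (j in seq_len(nrow(b))) {
      nxt <- empty_segments()
      for (k in seq_len(nrow(cur))) {
        s <- cur[k, 1]; e <- cur[k, 2]
        bs <- b[j, 1]; be <- b[j, 2]
        if (be <= s || bs >= e) {
          nxt <- rbind(nxt, cur[k, , drop = FALSE])
        } else {
          if (bs > s) nxt <- rbind(nxt, c(s, bs))
          if (be < e) nxt <- rbind(nxt, c(be, e))
        }
      }
      cur <- nxt
      if (nrow(cur) == 0) break
    }
    pieces[[i]] <- cur
  }
  as_segments(do.call(rbind, pieces))
}

# Total length of the intersection between a segment list and one window.
overlap_duration <- function(seg, start, end) {
  seg <- as_segments(seg)
  if (nrow(seg) == 0) return(0)
  sum(pmax(0, pmin(seg[, 2], end) - pmax(seg[, 1], start)))
}

# Intersection of two disjoint sorted segment lists.
intersect_segments <- function(a, b) {
  a <- as_segments(a); b <- as_segments(b)
  if (nrow(a) == 0 || nrow(b) == 0) return(empty_segments())
  out <- empty_segments()
  for (i in seq_len(nrow(a))) {
    s <- pmax(a[i, 1], b[, 1]); e <- pmin(a[i, 2], b[, 2])
    keep <- e > s
    if (any(keep)) out <- rbind(out, cbind(s[keep], e[keep]))
  }
  as_segments(out)
}

# Jaccard index between two segment lists (duration of intersection over
# duration of union).
segments_jaccard <- function(a, b) {
  a <- merge_segments(as_segments(a)); b <- merge_segments(as_segments(b))
  inter <- total_duration(intersect_segments(a, b))
  uni <- total_duration(a) + total_duration(b) - inter
  if (uni == 0) return(NA_real_)
  inter / uni
}

# Convert a logical per-sample vector into half-open time segments.
runs_to_segments <- function(flag, fs) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (length(keep) == 0) return(empty_segments())
  as_segments(cbind((starts[keep] - 1L) / fs, ends[keep] / fs))
}

# Smallest 7-smooth integer >= n (keeps FFT lengths fast).
next_fast_len <- function(n) {
  n <- as.integer(ceiling(n))
  if (n <= 6) return(max(n, 1L))
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L, 7L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

# TRUE when `ok` holds on every window center in [centers[i],
# centers[i] + persist_s] AND the grid actually covers that horizon (a
# condition cannot be verified past the last window).
sustained_at <- function(ok, centers, i, persist_s) {
  step <- if (length(centers) > 1) stats::median(diff(centers)) else persist_s
  span <- which(centers >= centers[i] - 1e-9 &
                  centers <= centers[i] + persist_s + 1e-9)
  length(span) > 0 &&
    max(centers[span]) + step >= centers[i] + persist_s - 1e-9 &&
    all(ok[span])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
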