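# Centred moving-window helpers with shrink-to-valid edges.
#
# For window length W the window at (1-based) index i covers
# [i - floor(W/2), i + ceiling(W/2) - 1], intersected with the signal; sums
# are divided by the number of samples actually covered, so no samples are
# fabricated at the record edges.

window_bounds <- function(n, w) {
  half_lo <- w %/% 2L
  half_hi <- w - half_lo - 1L
  i <- seq_len(n)
  list(lo = pmax(1L, i - half_lo), hi = pmin(n, i + half_hi))
}

moving_sum <- function(x, w) {
  n <- length(x)
  b <- window_bounds(n, as.integer(w))
  cs <- c(0, cumsum(x))
  cs[b$hi + 1L] - cs[b$lo]
}

moving_count <- function(n, w) {
  b <- window_bounds(n, as.integer(w))
  b$hi - b$lo + 1L
}

moving_mean <- function(x, w) {
  moving_sum(x, w) / moving_count(length(x), w)
}

# sample standard deviation over the same centred windows (denominator n-1)
moving_sd <- function(x, w) {
  n <- length(x)
  cnt <- moving_count(n, w)
  s1 <- moving_sum(x, w)
  s2 <- moving_sum(x * x, w)
  v <- (s2 - s1 * s1 / cnt) / (cnt - 1)
  v[v < 0] <- 0  # guard against rounding
  sqrt(v)
}

ms_to_samples <- function(ms, fs) ms * fs / 1000

samples_to_ms <- function(idx, fs) idx * 1000 / fs

# wrap a pipeline stage so failures carry the stage identity
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("in stage '%s': %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}
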