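#' Second-order Shannon energy of the filtered PCG
#'
#' Computes, at every sample, the second-order Shannon energy
#' `ES(i) = -(1/N) * sum(x^2 * log(x^2))` over a centred moving window of
#' `window_n` samples advanced one sample at a time, preserving the full
#' sampling resolution (1 ms at 1 kHz). The transform emphasizes
#' medium-intensity oscillations (heart-sound components) over low-intensity
#' noise. The input is amplitude-normalized internally to `max(|x|) = 1`, so
#' the result is invariant to polarity and to any global amplitude scale.
#'
#' Conventions: natural logarithm; `0 * log(0) := 0`; the window at index `i`
#' covers `[i - N/2, i + N/2)` and shrinks to the valid part at the record
#' edges (the sum is divided by the number of samples actually covered).
#'
#' @param pcg_filtered numeric vector, band-passed PCG.
#' @param window_n integration window length in samples (default 20, i.e.
#'   20 ms at 1 kHz, the typical duration of a heart-sound component).
#' @return Numeric vector of raw Shannon energy, same length as the input.
#' @seealso [normalize_envelope()]
#' @export
shannon_energy <- function(pcg_filtered, window_n = 20) {
  x <- as.numeric(pcg_filtered)
  window_n <- as.integer(window_n)
  if (window_n < 2L) stop("window_n must be >= 2")
  if (window_n > length(x)) stop("window_n exceeds signal length")
  m <- max(abs(x))
  if (m > 0) x <- x / m
  x2 <- x * x
  u <- x2 * log(x2)
  u[x2 == 0] <- 0  # continuous extension of t*log(t) at 0
  -moving_mean(u, window_n)
}

#' Moving normalization of the Shannon-energy envelope
#'
#' At every sample, subtracts the mean and divides by the standard deviation
#' of the raw Shannon energy computed over a sliding window of `norm_window`
#' seconds centred at that sample, then clamps negative values to zero. The
#' normalization equalizes signal-quality drift along the record so one
#' global amplitude threshold suffices for detection. Stretches where the
#' windowed standard deviation is zero (signal-free regions) map to zero.
#'
#' A 1-s window always spans at least one full heart sound at physiological
#' heart rates; a 2-s window may be used at very low heart rates with no
#' practical effect on the detected component times.
#'
#' @param raw_se raw Shannon energy from [shannon_energy()].
#' @param fs sampling rate, Hz.
#' @param norm_window normalization window length, seconds.
#' @param window_n integration window used to produce `raw_se` (stored as
#'   metadata).
#' @return An object of class `envelope_signal`: list with `values`
#'   (nonnegative, same length as the PCG), `fs`, `window_n`, `norm_window`.
#' @export
normalize_envelope <- function(raw_se, fs = 1000, norm_window = 1,
                               window_n = 20) {
  x <- as.numeric(raw_se)
  w <- as.integer(round(norm_window * fs))
  if (w < 2L) stop("normalization window shorter than 2 samples")
  mu <- moving_mean(x, w)
  sd_ <- moving_sd(x, w)
  z <- ifelse(sd_ > 0, (x - mu) / sd_, 0)
  z[z < 0] <- 0
  structure(list(values = z, fs = fs, window_n = as.integer(window_n),
                 norm_window = norm_window),
            class = "envelope_signal")
}

#' @export
print.envelope_signal <- function(x, ...) {
  cat(sprintf("Shannon-energy envelope: %d samples at %g Hz (max %.2f)\n",
              length(x$values), x$fs, if (length(x$values)) max(x$values) else NA))
  invisible(x)
}

#' Export the envelope as a single-column CSV aligned 1:1 with the PCG
#' @param env an `envelope_signal`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_envelope_csv <- function(env, path) {
  stopifnot(inherits(env, "envelope_signal"))
  utils::write.csv(data.frame(envelope = env$values), path, row.names = FALSE)
  invisible(path)
}
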