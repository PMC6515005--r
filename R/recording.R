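#' Paired ECG/PCG recording
#'
#' Container for a simultaneously sampled single-channel ECG and
#' phonocardiogram (PCG). Both traces must have equal length and share one
#' sampling rate; every downstream millisecond conversion uses `fs`.
#'
#' All sample indices in this package are 0-based, so at the default
#' `fs = 1000` an index is also a time in milliseconds from the start of the
#' retained record.
#'
#' @param ecg numeric vector, ECG samples (arbitrary amplitude units).
#' @param pcg numeric vector, PCG samples (arbitrary amplitude units).
#' @param fs sampling rate in Hz.
#' @param t0 index of the first retained sample relative to acquisition start
#'   (0 after delay compensation).
#' @return An object of class `pcg_recording`: a list with elements `ecg`,
#'   `pcg`, `fs`, `t0`.
#' @examples
#' rec <- recording(sin(1:1000 / 50), rnorm(1000), fs = 1000)
#' rec
#' @export
recording <- function(ecg, pcg, fs = 1000, t0 = 0L) {
  ecg <- as.numeric(ecg)
  pcg <- as.numeric(pcg)
  if (length(ecg) != length(pcg)) {
    stop("ecg and pcg must have equal length (", length(ecg), " vs ",
         length(pcg), ")")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a single positive number")
  }
  structure(list(ecg = ecg, pcg = pcg, fs = fs, t0 = as.integer(t0)),
            class = "pcg_recording")
}

#' @export
print.pcg_recording <- function(x, ...) {
  cat("Paired ECG/PCG recording\n")
  cat(sprintf("  samples : %d (%.1f s at %g Hz)\n",
              length(x$ecg), length(x$ecg) / x$fs, x$fs))
  cat(sprintf("  t0      : %d samples\n", x$t0))
  invisible(x)
}

#' Length of a recording in samples
#' @param x a `pcg_recording`.
#' @export
length.pcg_recording <- function(x) length(x$ecg)
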