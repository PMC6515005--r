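#' Band-pass filter specification
#'
#' Holds the cutoffs and orders of the two conditioning filters:
#' the ECG FIR cascade (high-pass then low-pass, linear phase) and the PCG
#' band-pass (Chebyshev type I, applied with zero phase). Defaults are the
#' method's constants: ECG 10--35 Hz with two order-250 stages, PCG 20--100 Hz
#' order 5 with 0.5 dB pass-band ripple.
#'
#' The 10--35 Hz ECG band retains the main QRS energy while rejecting baseline
#' wander and powerline components; the 20--100 Hz PCG band retains the main
#' heart-sound components while strongly attenuating murmurs (200--600 Hz).
#'
#' @param ecg_hp_cutoff ECG high-pass cutoff, Hz.
#' @param ecg_lp_cutoff ECG low-pass cutoff, Hz.
#' @param ecg_fir_order FIR order per stage (taps per stage = order + 1).
#' @param pcg_low,pcg_high PCG band edges, Hz.
#' @param pcg_order Chebyshev order of the PCG band-pass.
#' @param pcg_ripple_db Chebyshev pass-band ripple, dB.
#' @return An object of class `filter_spec`.
#' @examples
#' filter_spec()
#' @export
filter_spec <- function(ecg_hp_cutoff = 10, ecg_lp_cutoff = 35,
                        ecg_fir_order = 250,
                        pcg_low = 20, pcg_high = 100,
                        pcg_order = 5, pcg_ripple_db = 0.5) {
  spec <- list(ecg_hp_cutoff = ecg_hp_cutoff, ecg_lp_cutoff = ecg_lp_cutoff,
               ecg_fir_order = as.integer(ecg_fir_order),
               pcg_low = pcg_low, pcg_high = pcg_high,
               pcg_order = as.integer(pcg_order),
               pcg_ripple_db = pcg_ripple_db)
  if (!(ecg_hp_cutoff > 0 && ecg_hp_cutoff < ecg_lp_cutoff)) {
    stop("require 0 < ecg_hp_cutoff < ecg_lp_cutoff")
  }
  if (!(pcg_low > 0 && pcg_low < pcg_high)) {
    stop("require 0 < pcg_low < pcg_high")
  }
  if (spec$ecg_fir_order < 2 || spec$ecg_fir_order %% 2L != 0L) {
    stop("ecg_fir_order must be a positive even integer (linear phase, integer group delay)")
  }
  structure(spec, class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat("Filter specification\n")
  cat(sprintf("  ECG : FIR cascade HP %g Hz + LP %g Hz, order %d per stage (delay %d samples)\n",
              x$ecg_hp_cutoff, x$ecg_lp_cutoff, x$ecg_fir_order, x$ecg_fir_order))
  cat(sprintf("  PCG : Chebyshev-I band-pass %g-%g Hz, order %d, %g dB ripple, zero phase\n",
              x$pcg_low, x$pcg_high, x$pcg_order, x$pcg_ripple_db))
  invisible(x)
}

# Hamming-window FIR stages; each order-n linear-phase stage delays n/2
# samples, so the cascade delay is exactly ecg_fir_order samples.
design_ecg_fir <- function(spec, fs) {
  if (spec$ecg_lp_cutoff >= fs / 2) stop("ecg_lp_cutoff must be below fs/2")
  list(hp = signal::fir1(spec$ecg_fir_order, spec$ecg_hp_cutoff / (fs / 2),
                         type = "high"),
       lp = signal::fir1(spec$ecg_fir_order, spec$ecg_lp_cutoff / (fs / 2),
                         type = "low"),
       delay = spec$ecg_fir_order)
}

design_pcg_iir <- function(spec, fs) {
  if (spec$pcg_high >= fs / 2) stop("pcg_high must be below fs/2")
  signal::cheby1(spec$pcg_order, spec$pcg_ripple_db,
                 c(spec$pcg_low, spec$pcg_high) / (fs / 2), type = "pass")
}

#' Band-pass filter the raw ECG
#'
#' Applies the cascade of two causal linear-phase FIR stages (high-pass, then
#' low-pass). The cascade group delay equals `ecg_fir_order` samples and is
#' reported in the `"delay"` attribute so [align_signals()] can compensate it.
#'
#' @param raw_ecg numeric vector of raw ECG samples.
#' @param spec a [filter_spec()].
#' @param fs sampling rate, Hz.
#' @return Filtered ECG, same length as the input, with attribute `delay`
#'   (group delay in samples).
#' @seealso [align_signals()]
#' @export
bandpass_ecg <- function(raw_ecg, spec = filter_spec(), fs = 1000) {
  raw_ecg <- as.numeric(raw_ecg)
  if (length(raw_ecg) <= 2L * spec$ecg_fir_order) {
    stop("ECG shorter than the filter transient: need more than ",
         2L * spec$ecg_fir_order, " samples, got ", length(raw_ecg))
  }
  if (any(!is.finite(raw_ecg))) stop("non-finite samples in raw_ecg")
  d <- design_ecg_fir(spec, fs)
  y <- as.numeric(signal::filter(d$lp, signal::filter(d$hp, raw_ecg)))
  attr(y, "delay") <- d$delay
  y
}

#' Zero-phase band-pass filter the raw PCG
#'
#' Applies the Chebyshev type-I band-pass forward and backward so the net
#' phase response is exactly zero: a symmetric burst keeps its peak index.
#' Record edges are handled by odd-symmetric mirror padding (up to 2 s)
#' before the forward-backward pass, which absorbs the filter ring-down.
#'
#' @inheritParams bandpass_ecg
#' @param raw_pcg numeric vector of raw PCG samples.
#' @return Filtered PCG, same length as the input.
#' @export
bandpass_pcg <- function(raw_pcg, spec = filter_spec(), fs = 1000) {
  raw_pcg <- as.numeric(raw_pcg)
  if (any(!is.finite(raw_pcg))) stop("non-finite samples in raw_pcg")
  h <- design_pcg_iir(spec, fs)
  # the order-5 narrow-band Chebyshev rings for well over a second; two
  # seconds of mirror padding keep the forward-backward transient below
  # double-precision noise in the retained region
  pad <- min(length(raw_pcg) - 1L, as.integer(2 * fs))
  if (length(raw_pcg) <= 3L * (spec$pcg_order + 1L)) {
    stop("PCG shorter than the forward-backward transient")
  }
  n <- length(raw_pcg)
  # odd-symmetric mirror extension about the first and last samples
  head_pad <- 2 * raw_pcg[1L] - raw_pcg[(pad + 1L):2L]
  tail_pad <- 2 * raw_pcg[n] - raw_pcg[(n - 1L):(n - pad)]
  x <- c(head_pad, raw_pcg, tail_pad)
  y <- as.numeric(signal::filter(h, x))
  y <- rev(as.numeric(signal::filter(h, rev(y))))
  y[(pad + 1L):(pad + n)]
}

#' Delay-compensate and co-register filtered ECG and PCG
#'
#' The causal FIR cascade delays the ECG by `ecg_delay` samples while the
#' zero-phase PCG filter delays nothing. Dropping the first `ecg_delay`
#' samples of the ECG and the last `ecg_delay` samples of the PCG restores
#' simultaneity and equal length.
#'
#' @param filtered_ecg ECG from [bandpass_ecg()].
#' @param filtered_pcg PCG from [bandpass_pcg()].
#' @param ecg_delay total ECG group delay in samples; defaults to the
#'   `"delay"` attribute of `filtered_ecg`.
#' @param fs sampling rate, Hz.
#' @return A [recording()] of the two aligned traces (`t0 = 0`).
#' @export
align_signals <- function(filtered_ecg, filtered_pcg,
                          ecg_delay = attr(filtered_ecg, "delay"),
                          fs = 1000) {
  if (is.null(ecg_delay)) stop("ecg_delay not given and no delay attribute found")
  ecg_delay <- as.integer(ecg_delay)
  if (length(filtered_ecg) != length(filtered_pcg)) {
    stop("filtered traces must have equal length before alignment")
  }
  n <- length(filtered_ecg)
  if (ecg_delay >= n) stop("delay (", ecg_delay, ") >= signal length (", n, ")")
  if (ecg_delay < 0L) stop("negative delay")
  if (ecg_delay == 0L) {
    return(recording(filtered_ecg, filtered_pcg, fs = fs, t0 = 0L))
  }
  recording(as.numeric(filtered_ecg)[(ecg_delay + 1L):n],
            as.numeric(filtered_pcg)[1L:(n - ecg_delay)],
            fs = fs, t0 = 0L)
}
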