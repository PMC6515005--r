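#' Per-beat R-referenced component timings
#'
#' For every detected beat, the delays in ms between each labeled component
#' peak and its reference R-peak: `r_s1m`, `r_s1t` and their difference
#' `s1_split` for the first heart sound; `r_s2a`, `r_s2p`, `s2_split` for the
#' second. `r_s1m` may be negative (the S1 window starts 50 ms before the
#' R-peak). Beats with a missing sound yield `NA` for that sound's fields;
#' degenerate single-lobe sounds (unresolved split) contribute no delay
#' parameters at all -- their single peak locates the sound, not a valve
#' component.
#'
#' @param sounds a `heart_sounds` table from [classify_sounds()].
#' @param peaks the `rpeak_series` the sounds refer to.
#' @return Data frame with one row per detected beat: `beat_index`, `r_ms`,
#'   and the six parameters in ms.
#' @export
beat_timings <- function(sounds, peaks) {
  stopifnot(inherits(peaks, "rpeak_series"))
  fs <- peaks$fs
  nb <- length(peaks$indices)
  na <- rep(NA_real_, nb)
  out <- data.frame(beat_index = seq_len(nb),
                    r_ms = samples_to_ms(peaks$indices, fs),
                    r_s1m = na, r_s1t = na, s1_split = na,
                    r_s2a = na, r_s2p = na, s2_split = na)
  if (nb == 0L || !nrow(sounds)) return(out)
  d1 <- samples_to_ms(sounds$c1 - sounds$ref_rpeak, fs)
  d2 <- samples_to_ms(sounds$c2 - sounds$ref_rpeak, fs)
  # a merged single-lobe sound has no resolved components: its peak is the
  # sound, not a valve component, so it contributes no delay parameters
  d1[sounds$degenerate] <- NA_real_
  d2[sounds$degenerate] <- NA_real_
  i1 <- sounds$label == "S1"
  i2 <- !i1
  out$r_s1m[sounds$beat[i1]] <- d1[i1]
  out$r_s1t[sounds$beat[i1]] <- d2[i1]
  out$s1_split[sounds$beat[i1]] <- d2[i1] - d1[i1]
  out$r_s2a[sounds$beat[i2]] <- d1[i2]
  out$r_s2p[sounds$beat[i2]] <- d2[i2]
  out$s2_split[sounds$beat[i2]] <- d2[i2] - d1[i2]
  out
}

#' Distribution summary of the timing parameters
#'
#' Per parameter: contributing beat count, mean, standard deviation, median,
#' interquartile range, and the central 95% range (empirical 2.5th--97.5th
#' percentiles).
#'
#' @param timings data frame from [beat_timings()].
#' @return Data frame of class `timing_summary`, one row per parameter.
#' @export
summarize_timings <- function(timings) {
  pars <- c("r_s1m", "r_s1t", "s1_split", "r_s2a", "r_s2p", "s2_split")
  if (!nrow(timings)) stop("no beats to summarize")
  rows <- lapply(pars, function(p) {
    v <- timings[[p]]
    v <- v[!is.na(v)]
    if (!length(v)) {
      return(data.frame(parameter = p, n = 0L, mean = NA_real_, sd = NA_real_,
                        median = NA_real_, iqr = NA_real_, p2.5 = NA_real_,
                        p97.5 = NA_real_))
    }
    q <- stats::quantile(v, c(0.025, 0.975), names = FALSE)
    data.frame(parameter = p, n = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else 0,
               median = stats::median(v), iqr = stats::IQR(v),
               p2.5 = q[1], p97.5 = q[2])
  })
  structure(do.call(rbind, rows), class = c("timing_summary", "data.frame"))
}

#' @export
print.timing_summary <- function(x, digits = 1, ...) {
  y <- as.data.frame(x)
  y[-(1:2)] <- lapply(y[-(1:2)], round, digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Ensemble-average signal-to-noise ratio of the filtered PCG
#'
#' `SNR = 20 * log10(AS / (4 * sigma_N))` where `AS` is the peak-to-peak
#' amplitude of the R-peak-synchronous ensemble-average waveform over one
#' mean cardiac cycle and `sigma_N` is the standard deviation of the
#' beat-aligned samples pooled over the 70%--85% portion of the mean cycle,
#' where no heart sound is expected; `4 * sigma_N` is the width of the 95%
#' band of a Gaussian noise distribution. Beats whose full cycle does not fit
#' in the record are excluded from the ensemble.
#'
#' @param pcg_filtered filtered, delay-compensated PCG samples.
#' @param peaks an `rpeak_series` with at least 10 peaks.
#' @return SNR in dB; `Inf` (with a warning) when the noise window is
#'   perfectly silent.
#' @export
compute_snr <- function(pcg_filtered, peaks) {
  stopifnot(inherits(peaks, "rpeak_series"))
  x <- as.numeric(pcg_filtered)
  if (length(peaks$indices) < 10L) stop("need at least 10 beats for a stable mean waveform")
  fs <- peaks$fs
  cyc <- as.integer(round(mean(diff(peaks$indices))))
  starts <- peaks$indices + 1L                      # 1-based cycle starts
  starts <- starts[starts + cyc - 1L <= length(x)]  # complete cycles only
  ens <- vapply(starts, function(s) x[s:(s + cyc - 1L)], numeric(cyc))
  mw <- rowMeans(ens)
  as_pp <- max(mw) - min(mw)
  quiet <- (floor(0.70 * cyc) + 1L):floor(0.85 * cyc)
  sigma <- stats::sd(as.numeric(ens[quiet, ]))
  if (!is.finite(sigma) || sigma == 0) {
    warning("silent noise window: SNR is unbounded")
    return(Inf)
  }
  20 * log10(as_pp / (4 * sigma))
}

#' Detection and classification scores
#'
#' S1 sensitivity is the percentage of detected R-peaks whose beat carries a
#' classified S1; S2 likewise; the overall sensitivity is the mean of the
#' two. When synthetic ground truth is supplied, a sound only counts as
#' correct if each of its component peaks lies within `gate_ms` of the true
#' component time of the same label, and specificity is the percentage of
#' detected sounds that match a true sound.
#'
#' @param sounds a `heart_sounds` table.
#' @param peaks the `rpeak_series` used for classification.
#' @param truth optional `ground_truth` from [generate_recording()].
#' @param gate_ms correctness gate for synthetic matching, ms.
#' @param snr_db optional SNR to carry in the report.
#' @return An object of class `validation_report`: list with
#'   `s1_sensitivity`, `s2_sensitivity`, `overall_sensitivity`,
#'   `specificity` (NA without truth), `heart_rate`, `n_rpeaks`, `snr_db`.
#' @export
detection_scores <- function(sounds, peaks, truth = NULL, gate_ms = 10,
                             snr_db = NA_real_) {
  stopifnot(inherits(peaks, "rpeak_series"))
  n_r <- length(peaks$indices)
  if (n_r == 0L) stop("zero R-peaks: sensitivity undefined")
  fs <- peaks$fs
  hr <- if (n_r >= 2L) 60000 / mean(diff(peaks$indices) / fs * 1000) else NA_real_

  s1 <- sounds[sounds$label == "S1", , drop = FALSE]
  s2 <- sounds[sounds$label == "S2", , drop = FALSE]

  if (is.null(truth)) {
    ok1 <- rep(TRUE, nrow(s1)); ok2 <- rep(TRUE, nrow(s2))
    spec <- NA_real_
  } else {
    stopifnot(inherits(truth, "ground_truth"))
    ok1 <- match_sounds(s1, truth$components$mitral_ms,
                        truth$components$tricuspid_ms, fs, gate_ms)
    ok2 <- match_sounds(s2, truth$components$aortic_ms,
                        truth$components$pulmonary_ms, fs, gate_ms)
    n_det <- nrow(s1) + nrow(s2)
    spec <- if (n_det) 100 * (sum(ok1) + sum(ok2)) / n_det else NA_real_
  }

  sens1 <- 100 * length(unique(s1$beat[ok1])) / n_r
  sens2 <- 100 * length(unique(s2$beat[ok2])) / n_r
  structure(list(s1_sensitivity = sens1, s2_sensitivity = sens2,
                 overall_sensitivity = mean(c(sens1, sens2)),
                 specificity = spec, heart_rate = hr, n_rpeaks = n_r,
                 snr_db = snr_db),
            class = "validation_report")
}

# greedy one-to-one matching of detected sounds to true component pairs:
# each detected sound may claim the closest unclaimed true beat whose two
# component times both lie within the gate; a degenerate sound carries one
# peak locating the merged sound, so it is gated against the nearer of the
# two true components
match_sounds <- function(s, true_c1_ms, true_c2_ms, fs, gate_ms) {
  if (!nrow(s)) return(logical(0))
  ok <- rep(FALSE, nrow(s))
  claimed <- rep(FALSE, length(true_c1_ms))
  c1_ms <- samples_to_ms(s$c1, fs)
  c2_ms <- samples_to_ms(s$c2, fs)
  for (k in order(c1_ms)) {
    d1 <- abs(true_c1_ms - c1_ms[k])
    hit <- if (s$degenerate[k]) {
      !claimed & pmin(d1, abs(true_c2_ms - c1_ms[k])) <= gate_ms
    } else {
      !claimed & d1 <= gate_ms & abs(true_c2_ms - c2_ms[k]) <= gate_ms
    }
    if (any(hit)) {
      j <- which(hit)[which.min(d1[hit])]
      claimed[j] <- TRUE
      ok[k] <- TRUE
    }
  }
  ok
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation report\n")
  cat(sprintf("  R-peaks     : %d (HR %.1f bpm)\n", x$n_rpeaks, x$heart_rate))
  if (is.finite(x$snr_db)) cat(sprintf("  PCG SNR     : %.1f dB\n", x$snr_db))
  cat(sprintf("  sensitivity : S1 %.1f%%, S2 %.1f%%, overall %.1f%%\n",
              x$s1_sensitivity, x$s2_sensitivity, x$overall_sensitivity))
  if (!is.na(x$specificity)) {
    cat(sprintf("  specificity : %.1f%%\n", x$specificity))
  }
  invisible(x)
}
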