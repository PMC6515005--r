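#' Segmentation tuning constants
#'
#' All rule constants of the detection/classification stage, with the
#' method's defaults: amplitude threshold 5% of the envelope maximum,
#' segment joining below 10% of the mean RR, false-positive pruning at
#' 20%/40% of the mean RR, S1 window from 50 ms before the R-peak to 18% of
#' the beat RR after it, 20-sample Shannon-energy window, 1-s normalization
#' window.
#'
#' @param amp_frac amplitude threshold fraction of the envelope maximum.
#' @param join_frac joining gap fraction of the mean RR.
#' @param fp_frac,fp_frac2 pruning fractions of the mean RR.
#' @param s1_pre_ms S1 window extension before the R-peak, ms.
#' @param s1_rr_frac S1/S2 boundary fraction of the beat RR.
#' @param se_window_n Shannon-energy integration window, samples.
#' @param norm_window_s envelope normalization window, seconds.
#' @param prominence_frac minimum component-lobe prominence as a fraction of
#'   the segment maximum (see [locate_components()]).
#' @return An object of class `seg_control`.
#' @export
seg_control <- function(amp_frac = 0.05, join_frac = 0.10,
                        fp_frac = 0.20, fp_frac2 = 0.40,
                        s1_pre_ms = 50, s1_rr_frac = 0.18,
                        se_window_n = 20, norm_window_s = 1,
                        prominence_frac = 0.02) {
  fr <- c(amp_frac, join_frac, fp_frac, fp_frac2, s1_rr_frac)
  if (any(fr <= 0 | fr >= 1)) stop("all fractions must lie in (0, 1)")
  structure(list(amp_frac = amp_frac, join_frac = join_frac,
                 fp_frac = fp_frac, fp_frac2 = fp_frac2,
                 s1_pre_ms = s1_pre_ms, s1_rr_frac = s1_rr_frac,
                 se_window_n = as.integer(se_window_n),
                 norm_window_s = norm_window_s,
                 prominence_frac = prominence_frac),
            class = "seg_control")
}

#' Segment a paired ECG/PCG recording into heart sounds and components
#'
#' Runs the full pipeline on a raw [recording()]: ECG band-pass (FIR cascade)
#' and delay compensation, R-peak detection, zero-phase PCG band-pass,
#' second-order Shannon-energy envelope with moving normalization,
#' amplitude/time-threshold segment detection, split and component
#' localization, false-positive pruning, S1/S2 classification, and per-beat
#' timing extraction.
#'
#' @param rec a [recording()] with raw (unfiltered) traces.
#' @param spec a [filter_spec()].
#' @param control a [seg_control()].
#' @return An object of class `hs_segmentation`: list with the aligned
#'   `recording`, `rpeaks`, `rr`, `envelope`, the candidate table before
#'   pruning (`candidates`), the classified `sounds` (see
#'   [classify_sounds()]), per-beat `timings` (see [beat_timings()]), and the
#'   `spec`/`control` used. Methods: `print`, `summary`, `coef`, `plot`.
#' @examples
#' cfg <- sim_config(duration_s = 30, seed = 1)
#' rec <- generate_recording(cfg)$recording
#' fit <- hs_segment(rec)
#' fit
#' coef(fit)
#' @export
hs_segment <- function(rec, spec = filter_spec(), control = seg_control()) {
  stopifnot(inherits(rec, "pcg_recording"), inherits(spec, "filter_spec"),
            inherits(control, "seg_control"))
  fs <- rec$fs

  fe <- with_stage("filtering", bandpass_ecg(rec$ecg, spec, fs))
  fp <- with_stage("filtering", bandpass_pcg(rec$pcg, spec, fs))
  al <- with_stage("filtering", align_signals(fe, fp, fs = fs))

  peaks <- with_stage("rpeaks", detect_r_peaks(al$ecg, fs))

  se <- with_stage("envelope",
                   shannon_energy(al$pcg, control$se_window_n))
  env <- with_stage("envelope",
                    normalize_envelope(se, fs, control$norm_window_s,
                                       control$se_window_n))

  if (length(peaks$indices) < 2L) {
    # no usable beat structure: nothing can be classified
    sounds <- empty_heart_sounds()
    return(structure(list(recording = al, spec = spec, control = control,
                          rpeaks = peaks, rr = NULL, envelope = env,
                          candidates = sounds[0, ], sounds = sounds,
                          timings = beat_timings(sounds, peaks)),
                     class = "hs_segmentation"))
  }

  rr <- with_stage("rpeaks", rr_statistics(peaks))

  segs <- with_stage("segmentation",
                     threshold_segments(env, rr$mean_rr, control$amp_frac,
                                        control$join_frac))
  cands <- with_stage("segmentation",
                      segment_candidates(env, segs, control$prominence_frac))
  pruned <- with_stage("segmentation",
                       prune_false_positives(cands, rr$mean_rr, fs,
                                             control$fp_frac,
                                             control$fp_frac2))
  sounds <- with_stage("segmentation",
                       classify_sounds(pruned, peaks, rr,
                                       control$s1_pre_ms,
                                       control$s1_rr_frac))
  timings <- with_stage("metrics", beat_timings(sounds, peaks))

  structure(list(recording = al, spec = spec, control = control,
                 rpeaks = peaks, rr = rr, envelope = env,
                 candidates = cands, sounds = sounds, timings = timings),
            class = "hs_segmentation")
}

#' @export
print.hs_segmentation <- function(x, ...) {
  n <- length(x$recording$ecg)
  fs <- x$recording$fs
  cat("Heart-sound segmentation\n")
  cat(sprintf("  record   : %.1f s at %g Hz\n", n / fs, fs))
  cat(sprintf("  R-peaks  : %d", length(x$rpeaks$indices)))
  if (!is.null(x$rr)) {
    cat(sprintf(" (mean RR %.1f ms, HR %.1f bpm)",
                x$rr$mean_rr, 60000 / x$rr$mean_rr))
  }
  cat("\n")
  cat(sprintf("  sounds   : %d S1, %d S2 (%d candidate segments, %d discarded)\n",
              sum(x$sounds$label == "S1"), sum(x$sounds$label == "S2"),
              nrow(x$candidates), nrow(attr(x$sounds, "discards"))))
  invisible(x)
}

#' Mean R-referenced timing parameters of a segmentation
#'
#' @param object an `hs_segmentation`.
#' @param ... unused.
#' @return Named numeric vector of the six mean timing parameters in ms:
#'   `r_s1m`, `r_s1t`, `s1_split`, `r_s2a`, `r_s2p`, `s2_split`.
#' @export
coef.hs_segmentation <- function(object, ...) {
  t <- object$timings
  vapply(c("r_s1m", "r_s1t", "s1_split", "r_s2a", "r_s2p", "s2_split"),
         function(p) mean(t[[p]], na.rm = TRUE), numeric(1))
}

#' Summarize a heart-sound segmentation
#'
#' Combines the per-parameter timing summary ([summarize_timings()]), the
#' ensemble-average PCG SNR ([compute_snr()]) and the detection scores
#' ([detection_scores()]).
#'
#' @param object an `hs_segmentation`.
#' @param truth optional `ground_truth` (synthetic records) enabling the
#'   correctness gate and specificity.
#' @param ... unused.
#' @return An object of class `summary.hs_segmentation`.
#' @export
summary.hs_segmentation <- function(object, truth = NULL, ...) {
  timing <- if (nrow(object$timings)) summarize_timings(object$timings) else NULL
  snr <- if (length(object$rpeaks$indices) >= 10L) {
    compute_snr(object$recording$pcg, object$rpeaks)
  } else NA_real_
  scores <- if (length(object$rpeaks$indices) >= 1L) {
    detection_scores(object$sounds, object$rpeaks, truth, snr_db = snr)
  } else NULL
  structure(list(timing = timing, snr_db = snr, scores = scores),
            class = "summary.hs_segmentation")
}

#' @export
print.summary.hs_segmentation <- function(x, ...) {
  if (!is.null(x$scores)) print(x$scores)
  if (!is.null(x$timing)) {
    cat("\nTiming parameters (ms):\n")
    print(x$timing)
  }
  invisible(x)
}

#' Plot a heart-sound segmentation
#'
#' Three stacked panels over a time window: filtered ECG with R-peaks,
#' filtered PCG, and the normalized Shannon-energy envelope with the
#' classified sounds (segment spans, split, and component peaks).
#'
#' @param x an `hs_segmentation`.
#' @param t_lim time window in seconds, length 2; defaults to the first 5 s.
#' @param ... unused.
#' @return `x`, invisibly.
#' @export
plot.hs_segmentation <- function(x, t_lim = NULL, ...) {
  fs <- x$recording$fs
  n <- length(x$recording$ecg)
  if (is.null(t_lim)) t_lim <- c(0, min(5, n / fs))
  idx <- max(1L, floor(t_lim[1] * fs)):min(n, ceiling(t_lim[2] * fs))
  tt <- (idx - 1) / fs

  op <- graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(op))

  graphics::plot(tt, x$recording$ecg[idx], type = "l", xlab = "",
                 ylab = "ECG", main = "Filtered ECG with R-peaks")
  rp <- x$rpeaks$indices[x$rpeaks$indices + 1 >= idx[1] &
                           x$rpeaks$indices + 1 <= idx[length(idx)]]
  graphics::points(rp / fs, x$recording$ecg[rp + 1], col = 2, pch = 19)

  graphics::plot(tt, x$recording$pcg[idx], type = "l", xlab = "",
                 ylab = "PCG", main = "Filtered PCG")

  graphics::plot(tt, x$envelope$values[idx], type = "l", xlab = "time (s)",
                 ylab = "SE", main = "Shannon-energy envelope")
  s <- x$sounds[x$sounds$c1 + 1 >= idx[1] & x$sounds$c1 + 1 <= idx[length(idx)], ]
  if (nrow(s)) {
    cols <- ifelse(s$label == "S1", "firebrick", "steelblue")
    graphics::rect(s$start / fs, 0, s$end / fs,
                   max(x$envelope$values[idx]) * 0.05,
                   col = grDevices::adjustcolor(cols, 0.4), border = NA)
    graphics::points(s$c1 / fs, x$envelope$values[s$c1 + 1], col = cols, pch = 17)
    graphics::points(s$c2 / fs, x$envelope$values[s$c2 + 1], col = cols, pch = 25)
    graphics::text((s$start + s$end) / 2 / fs,
                   max(x$envelope$values[idx]) * 0.9, s$label, col = cols)
  }
  invisible(x)
}
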