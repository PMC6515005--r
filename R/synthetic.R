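#' Configuration of the synthetic ECG/PCG generator
#'
#' The generator emulates the signal structure the segmentation method is
#' built for: an ECG as a P-QRS-T train of piecewise Gaussians at a jittered
#' RR interval, and a PCG in which every beat carries four Gaussian-windowed
#' tone bursts (mitral, tricuspid, aortic, pulmonary) at programmable delays
#' from the R-peak, plus band-limited broadband noise, optional systolic
#' murmurs (high-frequency noise bursts) and optional premature ventricular
#' contractions (a wide low-frequency biphasic ECG wave replacing the normal
#' beat, with no heart sounds).
#'
#' Default component delays are the means of a healthy adult cohort
#' (see [healthy_cohort_table()]); default beat-to-beat timing jitter is a
#' few ms per component, representative of healthy mechanical variability.
#' The default burst is a 50-Hz, 40-ms component (centre of the 20--100 Hz
#' heart-sound band); murmur noise is band-passed 200 Hz up to the band limit
#' representable at `fs`.
#'
#' @param duration_s record length, seconds.
#' @param fs sampling rate, Hz (the method's constants assume 1000).
#' @param heart_rate mean heart rate, bpm.
#' @param rr_jitter_ms standard deviation of the beat-to-beat RR interval, ms.
#' @param component_delays named numeric: mean delays from the R-peak in ms
#'   for `mitral`, `tricuspid`, `aortic`, `pulmonary`.
#' @param component_jitter_ms per-component timing jitter SD, ms (same order).
#' @param component_amplitudes relative burst amplitudes (same order).
#' @param burst_freq_hz burst carrier frequency, Hz.
#' @param burst_ms burst duration, ms (Gaussian window, `sigma = burst_ms/4`).
#' @param noise_std PCG additive-noise SD relative to the mitral amplitude.
#' @param ecg_noise_std ECG additive-noise SD relative to the R amplitude.
#' @param murmur logical: add a systolic murmur to every beat.
#' @param murmur_amp relative murmur amplitude.
#' @param pvc number of premature ventricular contractions to insert.
#' @param seed integer seed making the record fully reproducible.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(duration_s = 60, fs = 1000, heart_rate = 60,
                       rr_jitter_ms = 25,
                       component_delays = c(mitral = 43.9, tricuspid = 76.0,
                                            aortic = 371.3, pulmonary = 399.4),
                       component_jitter_ms = c(mitral = 4, tricuspid = 6,
                                               aortic = 5, pulmonary = 8),
                       component_amplitudes = c(mitral = 1.0, tricuspid = 0.85,
                                                aortic = 0.9, pulmonary = 0.75),
                       burst_freq_hz = 60, burst_ms = 30,
                       noise_std = 0.05, ecg_noise_std = 0.01,
                       murmur = FALSE, murmur_amp = 0.3,
                       pvc = 0L, seed = NULL) {
  nm <- c("mitral", "tricuspid", "aortic", "pulmonary")
  component_delays <- stats::setNames(as.numeric(component_delays), nm)
  component_jitter_ms <- stats::setNames(as.numeric(component_jitter_ms), nm)
  component_amplitudes <- stats::setNames(as.numeric(component_amplitudes), nm)
  if (heart_rate <= 0) stop("heart_rate must be positive")
  if (component_delays["tricuspid"] <= component_delays["mitral"]) {
    stop("tricuspid delay must exceed mitral delay")
  }
  if (component_delays["pulmonary"] <= component_delays["aortic"]) {
    stop("pulmonary delay must exceed aortic delay")
  }
  rr_ms <- 60000 / heart_rate
  if (component_delays["pulmonary"] + burst_ms >= 0.9 * rr_ms) {
    stop("infeasible geometry: pulmonary component plus burst does not fit ",
         "inside one RR interval at ", heart_rate, " bpm")
  }
  structure(list(duration_s = duration_s, fs = fs, heart_rate = heart_rate,
                 rr_jitter_ms = rr_jitter_ms,
                 component_delays = component_delays,
                 component_jitter_ms = component_jitter_ms,
                 component_amplitudes = component_amplitudes,
                 burst_freq_hz = burst_freq_hz, burst_ms = burst_ms,
                 noise_std = noise_std, ecg_noise_std = ecg_noise_std,
                 murmur = isTRUE(murmur), murmur_amp = murmur_amp,
                 pvc = as.integer(pvc), seed = seed),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Synthetic ECG/PCG configuration: %.0f s at %g Hz, %g bpm\n",
              x$duration_s, x$fs, x$heart_rate))
  cat("  component delays (ms): ",
      paste(sprintf("%s %.1f", names(x$component_delays), x$component_delays),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  noise sd %.3g, murmur %s, PVC %d, seed %s\n",
              x$noise_std, if (x$murmur) "on" else "off", x$pvc,
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

add_gauss <- function(x, centre, sigma, amp, fs) {
  # add amp * exp(-(t-centre)^2 / 2 sigma^2); centre/sigma in samples
  lo <- max(1L, as.integer(floor(centre - 5 * sigma)))
  hi <- min(length(x), as.integer(ceiling(centre + 5 * sigma)))
  if (lo > hi) return(x)
  i <- lo:hi
  x[i] <- x[i] + amp * exp(-(i - centre)^2 / (2 * sigma^2))
  x
}

add_burst <- function(x, centre, sigma, amp, freq, fs) {
  lo <- max(1L, as.integer(floor(centre - 4 * sigma)))
  hi <- min(length(x), as.integer(ceiling(centre + 4 * sigma)))
  if (lo > hi) return(x)
  i <- lo:hi
  x[i] <- x[i] + amp * cos(2 * pi * freq * (i - centre) / fs) *
    exp(-(i - centre)^2 / (2 * sigma^2))
  x
}

#' Generate a synthetic paired ECG/PCG recording with ground truth
#'
#' Beats are scheduled at a jittered RR interval starting 0.5 s into the
#' record; only beats whose full cardiac cycle (through the pulmonary burst)
#' fits inside the record are generated, so the record ends after the last
#' complete cycle. Per beat, the four component times are drawn around the
#' configured means; within each sound the two components are sorted so the
#' earlier burst is always the first (mitral/aortic) component of the truth.
#'
#' @param cfg a [sim_config()].
#' @return List with `recording` (a [recording()]) and `truth`, an object of
#'   class `ground_truth`: `true_rpeaks` (0-based sample indices of non-PVC
#'   R-peaks), `components` (data frame of per-beat absolute component times
#'   in ms), `pvc_beats` (0-based sample indices of PVC centres).
#' @examples
#' sim <- generate_recording(sim_config(duration_s = 20, seed = 42))
#' sim$truth$true_rpeaks[1:3]
#' @export
generate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    fs <- cfg$fs
    n <- as.integer(round(cfg$duration_s * fs))
    rr_smp <- 60 / cfg$heart_rate * fs
    sig_b <- cfg$burst_ms / 6 / 1000 * fs  # burst SD: duration = +/- 3 SD

    ecg <- numeric(n)
    pcg <- numeric(n)

    # schedule beats: drop any whose full cycle does not fit in the record,
    # leaving a 0.3-s sound-free run-out so the final cycle stays fully
    # analyzable after filter-delay compensation trims the record tail
    beat_at <- 0.5 * fs
    beats <- numeric(0)
    max_extent <- (cfg$component_delays["pulmonary"] +
                     3 * cfg$component_jitter_ms["pulmonary"]) / 1000 * fs +
      4 * sig_b + 0.3 * fs
    repeat {
      if (beat_at + max_extent > n) break
      beats <- c(beats, beat_at)
      rr_k <- rr_smp + stats::rnorm(1, 0, cfg$rr_jitter_ms / 1000 * fs)
      rr_k <- max(rr_k, 0.5 * rr_smp, 0.35 * fs)
      beat_at <- beat_at + rr_k
    }
    nb <- length(beats)
    if (nb < 1L) stop("record too short for a single cardiac cycle")

    is_pvc <- rep(FALSE, nb)
    if (cfg$pvc > 0L) {
      if (cfg$pvc >= nb - 2L) stop("more PVCs than available interior beats")
      is_pvc[sample(2:(nb - 1L), cfg$pvc)] <- TRUE
    }

    comp <- matrix(NA_real_, nb, 4,
                   dimnames = list(NULL, names(cfg$component_delays)))
    for (k in seq_len(nb)) {
      b <- beats[k]
      if (is_pvc[k]) {
        # wide low-frequency biphasic deflection, no heart sounds
        half <- 0.075 * fs
        lo <- max(1L, as.integer(b - half)); hi <- min(n, as.integer(b + half))
        i <- lo:hi
        ecg[i] <- ecg[i] + 0.8 * sin(2 * pi * (i - b + half) / (2 * half))
        next
      }
      ecg <- add_gauss(ecg, b - 0.160 * fs, 0.020 * fs, 0.15, fs)  # P
      ecg <- add_gauss(ecg, b - 0.020 * fs, 0.005 * fs, -0.10, fs) # Q
      ecg <- add_gauss(ecg, b, 0.009 * fs, 1.0, fs)                # R
      ecg <- add_gauss(ecg, b + 0.022 * fs, 0.006 * fs, -0.15, fs) # S
      ecg <- add_gauss(ecg, b + 0.260 * fs, 0.045 * fs, 0.30, fs)  # T

      d <- cfg$component_delays +
        stats::rnorm(4, 0, cfg$component_jitter_ms)
      d[1:2] <- sort(d[1:2])  # earlier burst is the first component
      d[3:4] <- sort(d[3:4])
      comp[k, ] <- b + d / 1000 * fs  # absolute sample positions
      freqs <- rep(cfg$burst_freq_hz, length.out = 4)
      for (j in 1:4) {
        pcg <- add_burst(pcg, comp[k, j], sig_b,
                         cfg$component_amplitudes[j], freqs[j], fs)
      }
      if (cfg$murmur) {
        m_lo <- as.integer(comp[k, 2] + 4 * sig_b)
        m_hi <- as.integer(comp[k, 3] - 4 * sig_b)
        if (m_hi - m_lo > 0.05 * fs) {
          i <- m_lo:m_hi
          w <- 0.5 - 0.5 * cos(2 * pi * seq_along(i) / length(i))  # Hann
          hi_band <- c(200, min(450, 0.45 * fs)) / (fs / 2)
          mm <- as.numeric(signal::filter(signal::butter(4, hi_band, "pass"),
                                          stats::rnorm(length(i))))
          mm <- mm / max(stats::sd(mm), .Machine$double.eps)
          pcg[i] <- pcg[i] + cfg$murmur_amp * w * mm
        }
      }
    }

    if (cfg$noise_std > 0) {
      acq_lp <- signal::butter(4, min(262, 0.48 * fs) / (fs / 2), "low")
      pcg <- pcg + as.numeric(signal::filter(acq_lp,
                                             stats::rnorm(n, 0, cfg$noise_std)))
    }
    if (cfg$ecg_noise_std > 0) {
      ecg <- ecg + stats::rnorm(n, 0, cfg$ecg_noise_std)
    }

    normal <- which(!is_pvc)
    components <- data.frame(beat = seq_along(normal),
                             mitral_ms = samples_to_ms(comp[normal, 1], fs),
                             tricuspid_ms = samples_to_ms(comp[normal, 2], fs),
                             aortic_ms = samples_to_ms(comp[normal, 3], fs),
                             pulmonary_ms = samples_to_ms(comp[normal, 4], fs))
    truth <- structure(list(true_rpeaks = as.integer(round(beats[normal])),
                            components = components,
                            pvc_beats = as.integer(round(beats[is_pvc]))),
                       class = "ground_truth")
    list(recording = recording(ecg, pcg, fs = fs), truth = truth,
         config = cfg)
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Ground truth: %d beats, %d PVCs\n",
              length(x$true_rpeaks), length(x$pvc_beats)))
  invisible(x)
}

# peak-to-peak amplitude of the R-synchronous ensemble-average waveform
ensemble_pp <- function(pcg_filtered, rpeaks_idx, fs) {
  x <- as.numeric(pcg_filtered)
  cyc <- as.integer(round(mean(diff(rpeaks_idx))))
  starts <- rpeaks_idx + 1L
  starts <- starts[starts + cyc - 1L <= length(x)]
  acc <- numeric(cyc)
  for (s in starts) acc <- acc + x[s:(s + cyc - 1L)]
  mw <- acc / length(starts)
  max(mw) - min(mw)
}

#' Noise level needed for a target ensemble-average SNR
#'
#' Inverts the SNR definition for the generator: the ensemble-average
#' peak-to-peak amplitude `AS` is measured on a noiseless calibration record
#' generated from `cfg` (so timing-jitter smearing of the mean waveform is
#' accounted for), the white-noise-to-filtered-noise gain of the acquisition
#' low-pass plus the zero-phase 20--100 Hz band-pass is computed from the
#' cascade impulse response, and the white-noise SD achieving
#' `20*log10(AS / (4*sigma_N)) = target_db` is returned.
#'
#' @param cfg a [sim_config()].
#' @param target_db target SNR in dB.
#' @param spec [filter_spec()] used for the PCG band-pass.
#' @param calib_s calibration record length, seconds.
#' @return White-noise standard deviation to use as `noise_std`.
#' @export
noise_for_snr <- function(cfg, target_db, spec = filter_spec(),
                          calib_s = 60) {
  cfg0 <- cfg
  cfg0$duration_s <- calib_s
  cfg0$noise_std <- 0
  cfg0$ecg_noise_std <- 0
  cfg0$murmur <- FALSE
  cfg0$pvc <- 0L
  sim <- generate_recording(cfg0)
  fp <- bandpass_pcg(sim$recording$pcg, spec, cfg$fs)
  as_pp <- ensemble_pp(fp, sim$truth$true_rpeaks, cfg$fs)

  # white-noise gain through acquisition LP + zero-phase band-pass
  # (impulse centred away from the reflect-padded edges)
  acq_lp <- signal::butter(4, min(262, 0.48 * cfg$fs) / (cfg$fs / 2), "low")
  e <- numeric(8192); e[4096] <- 1
  h <- bandpass_pcg(as.numeric(signal::filter(acq_lp, e)), spec, cfg$fs)
  g <- sqrt(sum(h^2))

  sigma_n <- as_pp / (4 * 10^(target_db / 20))
  sigma_n / g
}

#' The bundled healthy-adult cohort timing table
#'
#' Per-subject heart rate, filtered-PCG SNR and mean component delays
#' (mitral, tricuspid, aortic, pulmonary; ms from the R-peak) for 24 healthy
#' adults spanning 55--90 bpm, used to program cohort simulations that cover
#' the physiological range of component timings.
#'
#' @return Data frame with columns `subject`, `hr_bpm`, `snr_db`, `s1m`,
#'   `s1t`, `s2a`, `s2p`.
#' @export
healthy_cohort_table <- function() {
  data.frame(
    subject = sprintf("subj_%02d", 1:24),
    hr_bpm = c(66, 82, 80, 66, 68, 63, 63, 55, 78, 56, 56, 63,
               84, 56, 65, 61, 67, 87, 86, 62, 65, 56, 76, 66),
    snr_db = c(33.7, 13.9, 16.1, 20.7, 28.3, 18.7, 27.2, 28.8, 15.0, 18.3,
               30.2, 24.4, 14.7, 27.7, 16.2, 14.2, 20.7, 21.9, 19.0, 25.4,
               12.5, 24.2, 14.4, 27.5),
    s1m = c(45.0, 20.7, 33.3, 66.7, 36.7, 41.5, 49.9, 45.8, 17.9, 41.5,
            39.2, 36.9, 39.2, 53.1, 32.4, 58.8, 23.8, 58.6, 43.6, 51.0,
            61.2, 59.5, 42.1, 54.0),
    s1t = c(64.3, 72.4, 63.9, 123.3, 50.2, 74.2, 69.5, 62.1, 72.1, 65.8,
            60.3, 77.5, 60.5, 76.6, 57.1, 110.5, 87.4, 94.0, 68.7, 85.0,
            98.5, 90.3, 68.6, 71.4),
    s2a = c(360.2, 328.0, 337.8, 429.7, 353.3, 398.8, 372.0, 392.3, 342.8,
            371.1, 379.7, 391.6, 361.7, 394.9, 351.1, 407.3, 360.8, 345.8,
            340.7, 407.6, 395.1, 382.1, 352.1, 355.0),
    s2p = c(382.5, 346.3, 348.1, 450.1, 368.3, 447.8, 407.8, 413.2, 386.4,
            390.4, 391.6, 451.9, 393.6, 423.0, 392.8, 433.4, 384.7, 370.1,
            360.3, 437.8, 424.2, 403.3, 387.6, 389.4),
    stringsAsFactors = FALSE)
}

#' Generate a cohort of synthetic recordings
#'
#' One record per row of `delay_table`, each programmed with that subject's
#' heart rate and component-delay means, with the per-record noise level
#' calibrated to the subject's SNR (floored at `snr_floor_db`). Per-record
#' seeds are derived deterministically from the master seed.
#'
#' @param n number of records; rows of `delay_table` are recycled with a
#'   warning if `n` exceeds them.
#' @param base_cfg a [sim_config()] providing all settings not taken from the
#'   table (duration, jitter, burst, amplitudes, ...).
#' @param delay_table data frame as [healthy_cohort_table()].
#' @param seed master seed.
#' @param snr_floor_db lower bound applied to the per-record target SNR; set
#'   `NULL` (or omit the `snr_db` column) to keep `base_cfg$noise_std`.
#' @return List of length `n`; each element is the [generate_recording()]
#'   result (elements `recording`, `truth`, `config`).
#' @export
generate_cohort <- function(n, base_cfg = sim_config(),
                            delay_table = healthy_cohort_table(),
                            seed = 1, snr_floor_db = 13) {
  stopifnot(n >= 1)
  if (n > nrow(delay_table)) {
    warning("delay_table shorter than n: recycling rows")
  }
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, n))
  lapply(seq_len(n), function(k) {
    row <- delay_table[(k - 1L) %% nrow(delay_table) + 1L, ]
    cfg <- base_cfg
    cfg$heart_rate <- row$hr_bpm
    cfg$component_delays[] <- c(row$s1m, row$s1t, row$s2a, row$s2p)
    cfg$seed <- seeds[k]
    cfg <- do.call(sim_config, unclass(cfg))  # revalidate geometry
    if (!is.null(snr_floor_db) && "snr_db" %in% names(delay_table)) {
      cfg$noise_std <- noise_for_snr(cfg, max(row$snr_db, snr_floor_db))
    }
    generate_recording(cfg)
  })
}
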