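# Shared fixtures: small synthetic records and cached segmentations.
# Everything is generated in code under fixed seeds; nothing is stored on disk.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a clean 60-s default-configuration record with its segmentation
clean_sim <- function() {
  cached("clean_sim", {
    sim <- generate_recording(sim_config(duration_s = 60, seed = 101,
                                         noise_std = 0.02))
    sim$fit <- hs_segment(sim$recording)
    sim
  })
}

# noiseless record for tight timing checks
silent_sim <- function() {
  cached("silent_sim", {
    sim <- generate_recording(sim_config(duration_s = 60, seed = 77,
                                         noise_std = 0, ecg_noise_std = 0))
    sim$fit <- hs_segment(sim$recording)
    sim
  })
}

# build an envelope_signal directly from raw values (unit tests of the
# segment-level operations)
env_from_values <- function(v, fs = 1000) {
  structure(list(values = as.numeric(v), fs = fs, window_n = 20L,
                 norm_window = 1), class = "envelope_signal")
}

rpeaks_at <- function(idx, fs = 1000) {
  structure(list(indices = as.integer(idx), fs = fs), class = "rpeak_series")
}

# independent frequency-response evaluation of an FIR filter (plain DFT sum)
fir_response <- function(b, f, fs) {
  vapply(f, function(fi) {
    w <- 2 * pi * fi / fs
    abs(sum(b * exp(-1i * w * (seq_along(b) - 1))))
  }, numeric(1))
}

# independent two-pass oracle for threshold_segments: explicit sample scan,
# then pairwise joining of runs separated by less than 10% of the mean RR
naive_threshold_join <- function(v, mean_rr, fs = 1000) {
  thr <- 0.05 * max(v)
  above <- v > thr
  segs <- list()
  i <- 1
  while (i <= length(v)) {
    if (above[i]) {
      j <- i
      while (j < length(v) && above[j + 1]) j <- j + 1
      segs[[length(segs) + 1]] <- c(i - 1, j)  # 0-based half-open
      i <- j + 1
    } else i <- i + 1
  }
  if (!length(segs)) return(matrix(integer(0), ncol = 2))
  gap_max <- 0.10 * mean_rr * fs / 1000
  out <- segs[[1]]
  res <- list()
  for (s in segs[-1]) {
    if (s[1] - out[2] < gap_max) out[2] <- s[2] else {
      res[[length(res) + 1]] <- out; out <- s
    }
  }
  res[[length(res) + 1]] <- out
  do.call(rbind, res)
}

# per-beat component errors of a segmentation against ground truth (ms)
component_errors <- function(fit, truth, label) {
  tc <- truth$components
  s <- fit$sounds[fit$sounds$label == label, , drop = FALSE]
  t1 <- if (label == "S1") tc$mitral_ms else tc$aortic_ms
  t2 <- if (label == "S1") tc$tricuspid_ms else tc$pulmonary_ms
  i <- match(s$beat, tc$beat)
  fs <- fit$recording$fs
  data.frame(beat = s$beat, degenerate = s$degenerate,
             e1 = s$c1 * 1000 / fs - t1[i],
             e2 = s$c2 * 1000 / fs - t2[i],
             true_split = t2[i] - t1[i])
}
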