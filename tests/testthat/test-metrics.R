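test_that("beat timings are simple differences in ms", {
  peaks <- rpeaks_at(c(1000, 2000))
  sounds <- structure(
    data.frame(ref_rpeak = c(1000L, 1000L), beat = c(1L, 1L),
               label = c("S1", "S2"),
               c1 = c(1000L, 1360L), c2 = c(1020L, 1382L),
               split = c(1010L, 1370L), start = c(980L, 1340L),
               end = c(1040L, 1400L), degenerate = FALSE, env_c1 = 1,
               component_1 = c("mitral", "aortic"),
               component_2 = c("tricuspid", "pulmonary")),
    class = c("heart_sounds", "data.frame"))
  bt <- beat_timings(sounds, peaks)
  expect_equal(nrow(bt), 2)
  expect_equal(bt$r_s1m[1], 0)          # component exactly at the R-peak
  expect_equal(bt$r_s1t[1], 20)
  expect_equal(bt$s1_split[1], 20)
  expect_equal(bt$r_s2a[1], 360)
  expect_equal(bt$s2_split[1], 22)
  expect_true(all(is.na(unlist(bt[2, 3:8]))))  # beat without sounds
})

test_that("programmed subject delays are recovered within 3 ms", {
  # subject-01-style configuration, noiseless for a tight check
  cfg <- sim_config(duration_s = 120, heart_rate = 66,
                    component_delays = c(mitral = 45.0, tricuspid = 64.3,
                                         aortic = 360.2, pulmonary = 382.5),
                    noise_std = 0, ecg_noise_std = 0, seed = 55)
  sim <- generate_recording(cfg)
  fit <- hs_segment(sim$recording)
  got <- coef(fit)
  expect_equal(got[["r_s1m"]], 45.0, tolerance = 3 / 45)
  expect_equal(got[["r_s1t"]], 64.3, tolerance = 3 / 64.3)
  expect_lt(abs(got[["s1_split"]] - 19.3), 3)
  expect_lt(abs(got[["r_s2a"]] - 360.2), 3)
  expect_lt(abs(got[["r_s2p"]] - 382.5), 3)
  expect_lt(abs(got[["s2_split"]] - 22.4), 3)
})

test_that("timing summaries match a direct statistics oracle", {
  t0 <- data.frame(beat_index = 1:5, r_ms = 0,
                   r_s1m = c(40, 41, 42, 43, 44), r_s1t = 60, s1_split = 20,
                   r_s2a = NA_real_, r_s2p = NA_real_, s2_split = NA_real_)
  ts <- summarize_timings(t0)
  r <- ts[ts$parameter == "r_s1m", ]
  expect_equal(r$n, 5L)
  expect_equal(r$mean, mean(40:44))
  expect_equal(r$sd, sd(40:44))
  expect_equal(r$median, 42)
  expect_equal(r$iqr, IQR(40:44))
  expect_equal(unlist(r[c("p2.5", "p97.5")], use.names = FALSE),
               unname(quantile(40:44, c(0.025, 0.975))))
  cte <- ts[ts$parameter == "s1_split", ]
  expect_equal(cte$sd, 0)               # constant parameter collapses
  expect_equal(cte$iqr, 0)
  expect_equal(cte$p2.5, cte$p97.5)
  expect_equal(ts[ts$parameter == "r_s2a", "n"], 0L)
  expect_error(summarize_timings(t0[0, ]), "no beats")
})

test_that("about 600 beats give a sub-2-ms confidence interval of the mean", {
  cfg <- sim_config(duration_s = 600, seed = 31,
                    component_jitter_ms = c(mitral = 2, tricuspid = 2,
                                            aortic = 2, pulmonary = 2))
  sim <- generate_recording(cfg)
  fit <- hs_segment(sim$recording)
  ts <- summarize_timings(fit$timings)
  for (p in c("r_s1m", "r_s1t", "r_s2a", "r_s2p")) {
    r <- ts[ts$parameter == p, ]
    expect_gt(r$n, 500)
    ci_width <- 2 * qt(0.975, r$n - 1) * r$sd / sqrt(r$n)
    expect_lte(ci_width, 2)
  }
})

test_that("the ensemble SNR matches its closed form and is scale-invariant", {
  cfg <- sim_config(duration_s = 120, seed = 66)
  target <- 18
  cfg$noise_std <- noise_for_snr(cfg, target)
  sim <- generate_recording(cfg)
  fit <- hs_segment(sim$recording)
  snr <- compute_snr(fit$recording$pcg, fit$rpeaks)
  expect_lt(abs(snr - target), 1)
  expect_equal(compute_snr(17.3 * fit$recording$pcg, fit$rpeaks), snr)
  # generator default noise keeps the reliability premise
  fitd <- clean_sim()$fit
  expect_gt(compute_snr(fitd$recording$pcg, fitd$rpeaks), 10)
})

test_that("a silent noise window yields the unbounded-SNR sentinel", {
  peaks <- rpeaks_at(seq(0, 11000, by = 1000))
  x <- numeric(12000)
  x[100 + seq(0, 11000, by = 1000)] <- 1  # a sound, nothing in 70-85%
  expect_warning(snr <- compute_snr(x, peaks), "silent")
  expect_identical(snr, Inf)
  expect_error(compute_snr(numeric(5000), rpeaks_at(c(0, 1000))), "10 beats")
})

test_that("sensitivity arithmetic follows the count definitions", {
  peaks <- rpeaks_at(seq(0, 99000, by = 1000))
  mk <- function(beats, label) {
    n <- length(beats)
    data.frame(ref_rpeak = (beats - 1L) * 1000L, beat = beats, label = label,
               c1 = (beats - 1L) * 1000L + 40L, c2 = (beats - 1L) * 1000L + 60L,
               split = 0L, start = 0L, end = 0L, degenerate = FALSE,
               env_c1 = 1, component_1 = "x", component_2 = "y")
  }
  sounds <- structure(rbind(mk(1:100, "S1"), mk(1:99, "S2")),
                      class = c("heart_sounds", "data.frame"))
  ds <- detection_scores(sounds, peaks)
  expect_equal(ds$s1_sensitivity, 100)
  expect_equal(ds$s2_sensitivity, 99)
  expect_equal(ds$overall_sensitivity, 99.5)
  expect_true(is.na(ds$specificity))
  expect_error(detection_scores(sounds, rpeaks_at(integer(0))), "zero R-peaks")
})

test_that("truth-gated scoring matches a brute-force matching oracle", {
  set.seed(9)
  fs <- 1000
  for (k in 1:10) {
    nb <- 12
    true_c1 <- seq(1000, by = 1000, length.out = nb) + 40
    true_c2 <- true_c1 + 25
    det1 <- true_c1 + sample(c(-25:25), nb, replace = TRUE)
    det2 <- true_c2 + sample(c(-25:25), nb, replace = TRUE)
    s <- data.frame(c1 = as.integer(det1), c2 = as.integer(det2),
                    degenerate = FALSE)
    got <- pcgseg:::match_sounds(s, true_c1, true_c2, fs, gate_ms = 10)
    # oracle: each detection is correct iff some unclaimed true beat has both
    # components within the gate; with 1-s spaced beats at most one true beat
    # can ever be in range, so the matching is unambiguous
    want <- abs(det1 - true_c1) <= 10 & abs(det2 - true_c2) <= 10
    expect_equal(got, unname(want))
  }
})

test_that("sensitivity does not increase with noise", {
  sens <- sapply(c(0.05, 0.4, 1.0), function(nz) {
    sim <- generate_recording(sim_config(duration_s = 60, seed = 33,
                                         noise_std = nz))
    fit <- hs_segment(sim$recording)
    detection_scores(fit$sounds, fit$rpeaks, sim$truth)$overall_sensitivity
  })
  expect_true(all(diff(sens) <= 1e-9))
})

test_that("splits are nonnegative for resolved beats", {
  fit <- clean_sim()$fit
  expect_true(all(fit$timings$s1_split >= 0, na.rm = TRUE))
  expect_true(all(fit$timings$s2_split >= 0, na.rm = TRUE))
})
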