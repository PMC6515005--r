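test_that("beat count and RR statistics match the configured heart rate", {
  sim <- generate_recording(sim_config(duration_s = 60, heart_rate = 60,
                                       seed = 1))
  nb <- length(sim$truth$true_rpeaks)
  expect_true(nb >= 58 && nb <= 61)
  rr <- diff(sim$truth$true_rpeaks)
  expect_lt(abs(mean(rr) - 1000), 3 * 25 / sqrt(length(rr)) + 2)
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- sim_config(duration_s = 30, seed = 123, murmur = TRUE, pvc = 1L)
  a <- generate_recording(cfg)
  b <- generate_recording(cfg)
  expect_identical(a$recording$ecg, b$recording$ecg)
  expect_identical(a$recording$pcg, b$recording$pcg)
  expect_identical(a$truth, b$truth)
})

test_that("ground truth is internally consistent", {
  sim <- generate_recording(sim_config(duration_s = 60, seed = 14, pvc = 2L))
  tc <- sim$truth$components
  expect_equal(nrow(tc), length(sim$truth$true_rpeaks))
  expect_equal(length(sim$truth$pvc_beats), 2L)
  expect_true(all(tc$tricuspid_ms >= tc$mitral_ms))
  expect_true(all(tc$pulmonary_ms >= tc$aortic_ms))
  expect_true(all(tc$aortic_ms > tc$tricuspid_ms))
})

test_that("infeasible geometry is rejected with an explanation", {
  expect_error(sim_config(heart_rate = 140), "infeasible geometry")
  expect_error(sim_config(component_delays = c(mitral = 50, tricuspid = 40,
                                               aortic = 360, pulmonary = 380)),
               "tricuspid")
})

test_that("burst and murmur spectra sit in their nominal bands", {
  band_fraction <- function(x, fs, lo, hi) {
    sp <- Mod(fft(x))^2
    f <- (seq_along(sp) - 1) * fs / length(sp)
    half <- f <= fs / 2
    sum(sp[half & f >= lo & f <= hi]) / sum(sp[half])
  }
  cfg <- sim_config(duration_s = 30, seed = 3, noise_std = 0,
                    ecg_noise_std = 0)
  sounds_only <- generate_recording(cfg)$recording$pcg
  expect_gte(band_fraction(sounds_only, 1000, 20, 100), 0.90)
  cfg_m <- sim_config(duration_s = 30, seed = 3, noise_std = 0,
                      ecg_noise_std = 0, murmur = TRUE, murmur_amp = 1,
                      component_amplitudes = c(mitral = 1e-9, tricuspid = 1e-9,
                                               aortic = 1e-9, pulmonary = 1e-9))
  murmur_only <- generate_recording(cfg_m)$recording$pcg
  expect_gte(band_fraction(murmur_only, 1000, 200, 600), 0.90)
})

test_that("noise calibrated by the SNR inversion hits its target", {
  cfg <- sim_config(duration_s = 120, seed = 19)
  cfg$noise_std <- noise_for_snr(cfg, 15)
  sim <- generate_recording(cfg)
  fit <- hs_segment(sim$recording)
  expect_lt(abs(compute_snr(fit$recording$pcg, fit$rpeaks) - 15), 1)
})

test_that("cohorts are table-programmed, deterministic, and recycle with warning", {
  tab <- healthy_cohort_table()
  expect_equal(nrow(tab), 24L)
  expect_true(all(tab$hr_bpm >= 55 & tab$hr_bpm <= 90))
  expect_true(all(tab$s1t > tab$s1m))
  expect_true(all(tab$s2p > tab$s2a))
  coh <- generate_cohort(3, sim_config(duration_s = 20), seed = 8,
                         snr_floor_db = NULL)
  for (k in 1:3) {
    expect_equal(unname(coh[[k]]$config$component_delays),
                 unname(unlist(tab[k, c("s1m", "s1t", "s2a", "s2p")])))
    expect_equal(coh[[k]]$config$heart_rate, tab$hr_bpm[k])
  }
  coh2 <- generate_cohort(3, sim_config(duration_s = 20), seed = 8,
                          snr_floor_db = NULL)
  expect_identical(coh[[2]]$recording$pcg, coh2[[2]]$recording$pcg)
  expect_warning(generate_cohort(25, sim_config(duration_s = 5,
                                                heart_rate = 75),
                                 delay_table = tab[1:2, ], seed = 1,
                                 snr_floor_db = NULL),
                 "recycling")
})

test_that("noiseless ground truth is recovered within the envelope tolerance", {
  sim <- silent_sim()
  for (lab in c("S1", "S2")) {
    err <- component_errors(sim$fit, sim$truth, lab)
    res <- err[!err$degenerate, ]
    expect_gt(nrow(res), 0.8 * nrow(err))
    sep <- res[res$true_split >= 30, ]  # disjoint bursts
    expect_true(all(abs(sep$e1) <= 3))
    expect_true(all(abs(sep$e2) <= 3))
  }
})
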