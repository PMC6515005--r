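test_that("thresholding and joining follow the 5% / 10%-RR rules", {
  env <- env_from_values(c(0, 0, 1, 1, 0, 0, 1, 1, 0))
  segs <- threshold_segments(env, mean_rr = 10)   # 10% RR = 1 sample < gap
  expect_equal(unname(segs), rbind(c(2L, 4L), c(6L, 8L)))
  merged <- threshold_segments(env, mean_rr = 1000)  # 100 ms >> 2-sample gap
  expect_equal(unname(merged), rbind(c(2L, 8L)))
  expect_equal(nrow(threshold_segments(env_from_values(numeric(20)), 1000)), 0)
})

test_that("thresholding matches the brute-force oracle on random envelopes", {
  set.seed(7)
  for (k in 1:20) {
    v <- pmax(0, rnorm(300, sd = 0.3) +
                ifelse(runif(300) < 0.1, runif(300, 1, 3), 0))
    rr <- runif(1, 50, 1500)
    got <- threshold_segments(env_from_values(v), rr)
    want <- naive_threshold_join(v, rr)
    expect_equal(unname(got), unname(want))
  }
})

test_that("component localization finds planted lobes and their valley", {
  x <- seq(0, 99)
  v <- 2 * exp(-(x - 30)^2 / 50) + 1.5 * exp(-(x - 70)^2 / 50)
  loc <- locate_components(env_from_values(v), 0L, 100L)
  expect_false(loc$degenerate)
  expect_equal(loc$c1, 30)
  expect_equal(loc$c2, 70)
  # the split is the deepest point between the lobes (brute-force check)
  between <- (loc$c1 + 2):loc$c2
  expect_equal(v[loc$split + 1], min(v[between]))
  expect_true(loc$c1 < loc$split && loc$split < loc$c2)
})

test_that("two interior minima of unequal depth: split lands at the deeper", {
  x <- seq(0, 119)
  v <- 2 * exp(-(x - 25)^2 / 40) + 1.1 * exp(-(x - 60)^2 / 30) +
    1.8 * exp(-(x - 95)^2 / 40)
  # three lobes -> two valleys; the rule brackets the two LARGEST lobes
  loc <- locate_components(env_from_values(v), 0L, 120L)
  expect_equal(loc$c1, 25)
  expect_equal(loc$c2, 95)
  between <- (25 + 2):95
  expect_equal(v[loc$split + 1], min(v[between]))
})

test_that("single lobes and sub-resolution doublets degenerate", {
  x <- seq(0, 59)
  v <- exp(-(x - 30)^2 / 60)
  loc <- locate_components(env_from_values(v), 0L, 60L)
  expect_true(loc$degenerate)
  expect_equal(loc$c1, 30)
  expect_equal(loc$c2, 30)
  # micro-ripple within half the integration window is not a second lobe
  v2 <- v + 0.05 * exp(-(x - 36)^2 / 4)
  loc2 <- locate_components(env_from_values(v2), 0L, 60L)
  expect_true(loc2$degenerate)
  expect_error(locate_components(env_from_values(v), 0L, 2L), "shorter")
})

test_that("false-positive pruning implements both RR-fraction rules", {
  cand <- function(c1_ms, env) {
    data.frame(start = c1_ms - 20L, end = c1_ms + 20L, split = c1_ms,
               c1 = c1_ms, c2 = c1_ms + 10L, degenerate = FALSE,
               env_c1 = env)
  }
  # rule (a): two first components 100 ms apart at mean RR 1000
  two <- rbind(cand(1000L, 5), cand(1100L, 3))
  kept <- prune_false_positives(two, mean_rr = 1000)
  expect_equal(kept$c1, 1000L)
  # rule (b): consecutive gaps 350/350 ms, both under 40% RR
  three <- rbind(cand(1000L, 5), cand(1350L, 2), cand(1700L, 4))
  kept3 <- prune_false_positives(three, mean_rr = 1000)
  expect_equal(kept3$c1, c(1000L, 1700L))
  # single candidate passes through
  one <- cand(500L, 1)
  expect_equal(prune_false_positives(one, 1000), one)
  expect_equal(nrow(prune_false_positives(one[0, ], 1000)), 0)
})

test_that("pruning is stable and leaves no violating pair", {
  set.seed(8)
  for (k in 1:10) {
    n <- sample(3:12, 1)
    cands <- data.frame(start = 0L, end = 0L, split = 0L,
                        c1 = sort(sample.int(10000, n)), c2 = 0L,
                        degenerate = FALSE, env_c1 = runif(n))
    rr <- runif(1, 400, 1200)
    out <- prune_false_positives(cands, rr)
    if (nrow(out) >= 2) expect_true(all(diff(out$c1) >= 0.2 * rr))
    expect_equal(prune_false_positives(out, rr), out)  # idempotent
  }
})

test_that("classification windows follow the 50 ms / 18% RR rules", {
  peaks <- rpeaks_at(c(1000, 2000, 3000))
  rr <- rr_statistics(peaks)
  mk <- function(c1) data.frame(start = c1 - 20L, end = c1 + 40L,
                                split = c1 + 15L, c1 = c1, c2 = c1 + 30L,
                                degenerate = FALSE, env_c1 = 1)
  s1 <- classify_sounds(mk(1040L), peaks, rr)    # 40 < 180 ms
  expect_equal(s1$label, "S1")
  expect_equal(s1$component_1, "mitral")
  expect_equal(s1$component_2, "tricuspid")
  expect_equal(s1$ref_rpeak, 1000L)
  s2 <- classify_sounds(mk(1350L), peaks, rr)    # 350 >= 180 ms
  expect_equal(s2$label, "S2")
  expect_equal(s2$component_1, "aortic")
  pre <- classify_sounds(mk(960L), peaks, rr)    # 40 ms before the R-peak
  expect_equal(pre$label, "S1")
  none <- classify_sounds(mk(940L), peaks, rr)   # 60 ms before: no window
  expect_equal(nrow(none), 0)
  expect_equal(nrow(attr(none, "discards")), 1)
})

test_that("at most one S1 and one S2 survive per cycle", {
  peaks <- rpeaks_at(c(1000, 2000))
  rr <- rr_statistics(peaks)
  mk <- function(c1, e) data.frame(start = c1 - 20L, end = c1 + 40L,
                                   split = c1 + 15L, c1 = c1, c2 = c1 + 30L,
                                   degenerate = FALSE, env_c1 = e)
  cands <- rbind(mk(1030L, 2), mk(1090L, 5), mk(1400L, 1), mk(1500L, 3))
  out <- classify_sounds(cands, peaks, rr)
  expect_equal(nrow(out), 2)
  expect_equal(out$c1[out$label == "S1"], 1090L)  # higher envelope wins
  expect_equal(out$c1[out$label == "S2"], 1500L)
  expect_true(any(attr(out, "discards")$reason == "duplicate in cycle"))
})

test_that("every classified sound satisfies its window invariant", {
  fit <- clean_sim()$fit
  fs <- fit$recording$fs
  pk <- fit$rpeaks$indices
  for (k in seq_len(nrow(fit$sounds))) {
    s <- fit$sounds[k, ]
    ref <- s$ref_rpeak
    nxt <- pk[match(ref, pk) + 1]
    rr_b <- if (is.na(nxt)) pcgseg:::ms_to_samples(fit$rr$mean_rr, fs) else nxt - ref
    if (s$label == "S1") {
      expect_gte(s$c1, ref - 50)
      expect_lte(s$c1, ref + 0.18 * rr_b)
    } else {
      expect_gte(s$c1, ref + 0.18 * rr_b)
    }
  }
  expect_true(all(table(fit$sounds$beat, fit$sounds$label) <= 1))
})

test_that("the full pipeline recovers each planted component on clean data", {
  sim <- silent_sim()
  nb <- length(sim$truth$true_rpeaks)
  expect_equal(length(sim$fit$rpeaks$indices), nb)
  for (lab in c("S1", "S2")) {
    err <- component_errors(sim$fit, sim$truth, lab)
    expect_equal(nrow(err), nb)  # one sound of each type per beat
    # per-beat tolerance applies where the two bursts do not overlap;
    # overlapping envelopes shift both peaks toward each other by design
    res <- err[!err$degenerate & err$true_split >= 30, ]
    expect_gt(nrow(res), 10)
    expect_true(all(abs(res$e1) <= 3))
    expect_true(all(abs(res$e2) <= 3))
  }
  # the programmed delays themselves (the means) are recovered tightly
  tc <- sim$truth$components
  tru <- c(mean(tc$mitral_ms - sim$truth$true_rpeaks),
           mean(tc$tricuspid_ms - sim$truth$true_rpeaks),
           mean(tc$aortic_ms - sim$truth$true_rpeaks),
           mean(tc$pulmonary_ms - sim$truth$true_rpeaks))
  got <- coef(sim$fit)[c("r_s1m", "r_s1t", "r_s2a", "r_s2p")]
  expect_true(all(abs(got - tru) <= 3))
})

test_that("null inputs produce no sounds", {
  set.seed(4)
  fitn <- hs_segment(recording(numeric(10000), rnorm(10000, 0, 0.3)))
  expect_equal(nrow(fitn$sounds), 0)
  fitz <- hs_segment(recording(numeric(5000), numeric(5000)))
  expect_equal(nrow(fitz$sounds), 0)
})

test_that("segmentation is deterministic", {
  sim <- clean_sim()
  f2 <- hs_segment(sim$recording)
  expect_identical(f2$sounds, sim$fit$sounds)
  expect_identical(f2$rpeaks$indices, sim$fit$rpeaks$indices)
  expect_identical(f2$envelope$values, sim$fit$envelope$values)
})

test_that("stage errors carry the stage identity", {
  expect_error(hs_segment(recording(numeric(100), numeric(100))),
               "in stage 'filtering'")
})
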