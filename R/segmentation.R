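#' Amplitude thresholding and gap joining of envelope segments
#'
#' Step 1--2 of the detection rules: candidate heart-sound segments are the
#' maximal runs of envelope samples above 5% of the global envelope maximum;
#' consecutive runs separated by less than 10% of the mean RR interval are
#' joined, so an under-threshold intercomponent split cannot break one sound
#' into two segments.
#'
#' @param env an `envelope_signal` from [normalize_envelope()].
#' @param mean_rr mean RR interval, ms.
#' @param amp_frac amplitude threshold as a fraction of the envelope maximum.
#' @param join_frac joining gap as a fraction of `mean_rr`.
#' @return Integer matrix with columns `start`, `end`: 0-based, half-open
#'   `[start, end)` sample intervals; zero rows if the envelope is all zero.
#' @export
threshold_segments <- function(env, mean_rr, amp_frac = 0.05,
                               join_frac = 0.10) {
  stopifnot(inherits(env, "envelope_signal"))
  if (!is.finite(mean_rr) || mean_rr <= 0) stop("mean_rr must be positive")
  v <- env$values
  empty <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (!length(v) || max(v) <= 0) return(empty)
  thr <- amp_frac * max(v)
  r <- rle(v > thr)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])  # 1-based inclusive
  if (!nrow(runs)) return(empty)

  gap_max <- ms_to_samples(join_frac * mean_rr, env$fs)
  out <- runs[1, , drop = FALSE]
  for (k in seq_len(nrow(runs))[-1]) {
    gap <- runs[k, 1] - out[nrow(out), 2] - 1L
    if (gap < gap_max) {
      out[nrow(out), 2] <- runs[k, 2]
    } else {
      out <- rbind(out, runs[k, , drop = FALSE])
    }
  }
  m <- cbind(start = out[, 1] - 1L, end = out[, 2])  # to 0-based half-open
  storage.mode(m) <- "integer"
  m
}

#' Locate the split and the two component peaks within a segment
#'
#' Steps 3--4 of the detection rules: the split is the deepest interior
#' local minimum of the envelope between the segment's two component lobes;
#' the first and second component peaks are the envelope maxima on
#' `[start, split]` and `[split, end)` respectively. Ties are resolved to
#' the earliest index.
#'
#' A local maximum only counts as a component lobe when it is prominent:
#' the envelope must rise and fall around it by at least `prominence_frac`
#' of the segment maximum. This guards the deepest-minimum search against
#' numerical ripple on the low segment flanks (where any micro-oscillation
#' would otherwise win the depth comparison); the split is then the deepest
#' point between the two largest prominent lobes. A segment with fewer than
#' two prominent lobes (single-lobe sound, unresolved split) is returned
#' degenerate with `split = c1 = c2 = argmax`.
#'
#' @param env an `envelope_signal`.
#' @param start,end 0-based half-open segment bounds (from
#'   [threshold_segments()]).
#' @param prominence_frac minimum lobe prominence as a fraction of the
#'   segment maximum.
#' @return List with 0-based indices `split`, `c1`, `c2` and logical
#'   `degenerate`.
#' @export
locate_components <- function(env, start, end, prominence_frac = 0.02,
                              min_sep = ceiling(env$window_n / 2)) {
  stopifnot(inherits(env, "envelope_signal"))
  if (end - start < 3L) stop("segment shorter than 3 samples")
  v <- env$values[(start + 1L):end]  # 1-based slice of [start, end)
  m <- length(v)
  degenerate <- function() {
    apex <- which.max(v)
    list(split = start + apex - 1L, c1 = start + apex - 1L,
         c2 = start + apex - 1L, degenerate = TRUE)
  }
  lobes <- prominent_maxima(v, prominence_frac * max(v))
  if (length(lobes) < 2L) return(degenerate())
  # dominant lobe, then the largest lobe at least min_sep away: two
  # components closer than half the integration window are below the
  # envelope's resolution and cannot be told apart from window ripple
  lobe1 <- lobes[order(-v[lobes], lobes)[1]]
  cand2 <- lobes[abs(lobes - lobe1) >= min_sep]
  if (!length(cand2)) return(degenerate())
  lobe2 <- cand2[order(-v[cand2], cand2)[1]]
  top2 <- sort(c(lobe1, lobe2))
  if (top2[2] - top2[1] < 2L) return(degenerate())
  between <- (top2[1] + 1L):(top2[2] - 1L)
  split <- between[which.min(v[between])]
  c1 <- which.max(v[1:split])
  c2 <- split - 1L + which.max(v[split:m])
  list(split = start + split - 1L, c1 = start + c1 - 1L,
       c2 = start + c2 - 1L, degenerate = FALSE)
}

# hysteresis scan for delta-prominent local maxima: a maximum is confirmed
# once the envelope has dropped delta below it, and a new one can only open
# after the envelope has risen delta above the intervening minimum; ties
# keep the earliest index
prominent_maxima <- function(v, delta) {
  maxima <- integer(0)
  rising <- TRUE
  cur_max <- v[1]; cur_max_i <- 1L
  cur_min <- v[1]
  for (i in seq_along(v)) {
    if (rising) {
      if (v[i] > cur_max) { cur_max <- v[i]; cur_max_i <- i }
      if (v[i] <= cur_max - delta) {
        maxima <- c(maxima, cur_max_i)
        rising <- FALSE
        cur_min <- v[i]
      }
    } else {
      if (v[i] < cur_min) cur_min <- v[i]
      if (v[i] >= cur_min + delta) {
        rising <- TRUE
        cur_max <- v[i]; cur_max_i <- i
      }
    }
  }
  maxima
}

empty_heart_sounds <- function() {
  empty <- data.frame(ref_rpeak = integer(0), beat = integer(0),
                      label = character(0), c1 = integer(0),
                      c2 = integer(0), split = integer(0),
                      start = integer(0), end = integer(0),
                      degenerate = logical(0), env_c1 = numeric(0),
                      component_1 = character(0), component_2 = character(0),
                      stringsAsFactors = FALSE)
  structure(empty,
            discards = data.frame(c1 = integer(0), reason = character(0)),
            class = c("heart_sounds", "data.frame"))
}

segment_candidates <- function(env, segments, prominence_frac = 0.02) {
  rows <- lapply(seq_len(nrow(segments)), function(k) {
    s <- segments[k, "start"]; e <- segments[k, "end"]
    if (e - s < 3L) return(NULL)  # too short to carry components
    loc <- locate_components(env, s, e, prominence_frac)
    data.frame(start = s, end = e, split = loc$split,
               c1 = loc$c1, c2 = loc$c2, degenerate = loc$degenerate,
               env_c1 = env$values[loc$c1 + 1L])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(start = integer(0), end = integer(0),
                      split = integer(0), c1 = integer(0), c2 = integer(0),
                      degenerate = logical(0), env_c1 = numeric(0))
  }
  out[order(out$c1), , drop = FALSE]
}

#' Remove false-positive candidate segments
#'
#' Step 5 of the detection rules, applied iteratively until stable:
#' (a) if two first components are closer than 20% of the mean RR interval,
#' the one with the lower envelope value is removed; (b) if two consecutive
#' pairs of first components are both closer than 40% of the mean RR
#' interval, the first component of the triple with the lowest envelope
#' value is removed.
#'
#' @param candidates data frame of candidate segments sorted by `c1`
#'   (columns `start`, `end`, `split`, `c1`, `c2`, `degenerate`, `env_c1`).
#' @param mean_rr mean RR interval, ms.
#' @param fs sampling rate, Hz.
#' @param fp_frac,fp_frac2 the 20% and 40% rule fractions.
#' @return The pruned candidate data frame.
#' @export
prune_false_positives <- function(candidates, mean_rr, fs = 1000,
                                  fp_frac = 0.20, fp_frac2 = 0.40) {
  if (!nrow(candidates)) return(candidates)
  cand <- candidates[order(candidates$c1), , drop = FALSE]
  lim1 <- ms_to_samples(fp_frac * mean_rr, fs)
  lim2 <- ms_to_samples(fp_frac2 * mean_rr, fs)
  repeat {
    if (nrow(cand) < 2L) break
    gaps <- diff(cand$c1)
    i <- which(gaps < lim1)
    if (length(i)) {
      pair <- c(i[1], i[1] + 1L)
      drop <- pair[which.min(cand$env_c1[pair])]
      cand <- cand[-drop, , drop = FALSE]
      next
    }
    if (nrow(cand) >= 3L) {
      j <- which(utils::head(gaps, -1) < lim2 & utils::tail(gaps, -1) < lim2)
      if (length(j)) {
        triple <- j[1] + 0:2
        drop <- triple[which.min(cand$env_c1[triple])]
        cand <- cand[-drop, , drop = FALSE]
        next
      }
    }
    break
  }
  cand
}

#' Classify candidate segments as first or second heart sounds
#'
#' Step 6 of the detection rules. Each candidate is referred to the nearest
#' preceding R-peak, or to the following one when its first component
#' precedes that peak by at most `s1_pre_ms`. With `RR` the interval
#' starting at the reference peak (the mean RR for the last beat): a
#' candidate whose first component lies within
#' `[ref - s1_pre_ms, ref + s1_rr_frac * RR]` is a first heart sound
#' (components mitral, tricuspid); one whose first component lies at or
#' beyond `ref + s1_rr_frac * RR` but before the next beat's S1 window is a
#' second heart sound (components aortic, pulmonary). Per cardiac cycle at
#' most one S1 and one S2 are retained (the larger first-component envelope
#' wins); everything else is discarded with a reason.
#'
#' @param candidates pruned candidate data frame (see
#'   [prune_false_positives()]).
#' @param peaks an `rpeak_series` with at least 2 peaks.
#' @param rr an `rr_stats` from [rr_statistics()].
#' @param s1_pre_ms S1 window extension before the R-peak, ms.
#' @param s1_rr_frac S1/S2 boundary as a fraction of the beat RR interval.
#' @return An object of class `heart_sounds`: data frame with one row per
#'   retained sound (`ref_rpeak`, `beat`, `label`, `c1`, `c2`, `split`,
#'   `start`, `end` as 0-based indices, `degenerate`, `env_c1`, component
#'   labels), with discarded candidates and reasons in attribute
#'   `"discards"`.
#' @export
classify_sounds <- function(candidates, peaks, rr,
                            s1_pre_ms = 50, s1_rr_frac = 0.18) {
  stopifnot(inherits(peaks, "rpeak_series"), inherits(rr, "rr_stats"))
  if (length(peaks$indices) < 2L) stop("need at least 2 R-peaks")
  fs <- peaks$fs
  pk <- peaks$indices
  pre <- ms_to_samples(s1_pre_ms, fs)
  mean_rr_smp <- ms_to_samples(rr$mean_rr, fs)

  nc <- nrow(candidates)
  if (nc == 0L) return(empty_heart_sounds())
  c1v <- candidates$c1
  npk <- length(pk)

  # reference beat: nearest preceding peak, or the next one if the first
  # component precedes it by no more than the pre-window
  b <- findInterval(c1v, pk)
  has_next <- b < npk
  adv <- has_next & (pk[pmin(b + 1L, npk)] - c1v <= pre)
  b[adv] <- b[adv] + 1L
  valid <- b >= 1L
  bi <- pmax(b, 1L)
  ref <- pk[bi]
  beat_rr <- ifelse(b < npk, pk[pmin(b + 1L, npk)] - ref, mean_rr_smp)
  bound <- ref + s1_rr_frac * beat_rr
  nxt_s1_start <- ifelse(b < npk, pk[pmin(b + 1L, npk)] - pre, Inf)

  is_s1 <- valid & c1v >= ref - pre & c1v <= bound
  is_s2 <- valid & !is_s1 & c1v >= bound & c1v < nxt_s1_start
  reason <- rep(NA_character_, nc)
  reason[!valid] <- "before first beat"
  reason[valid & !is_s1 & !is_s2] <- "outside both classification windows"

  keep <- which(is_s1 | is_s2)
  rows <- data.frame(
    ref_rpeak = as.integer(ref[keep]), beat = as.integer(b[keep]),
    label = ifelse(is_s1[keep], "S1", "S2"),
    c1 = candidates$c1[keep], c2 = candidates$c2[keep],
    split = candidates$split[keep],
    start = candidates$start[keep], end = candidates$end[keep],
    degenerate = candidates$degenerate[keep],
    env_c1 = candidates$env_c1[keep],
    component_1 = ifelse(is_s1[keep], "mitral", "aortic"),
    component_2 = ifelse(is_s1[keep], "tricuspid", "pulmonary"),
    stringsAsFactors = FALSE)

  # per cycle at most one S1 and one S2: highest first-component envelope wins
  if (nrow(rows)) {
    o <- order(rows$beat, rows$label, -rows$env_c1)
    dup <- duplicated(paste(rows$beat[o], rows$label[o]))
    dup_idx <- o[dup]
    reason[keep[dup_idx]] <- "duplicate in cycle"
    if (length(dup_idx)) rows <- rows[-dup_idx, , drop = FALSE]
    rows <- rows[order(rows$c1), , drop = FALSE]
  }
  discards <- data.frame(c1 = c1v[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  rownames(rows) <- NULL
  structure(rows, discards = discards, class = c("heart_sounds", "data.frame"))
}
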