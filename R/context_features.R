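# Knowledge-based per-sample feature maps derived from R-peak positions:
# the relative RR interval and the RR (sample) entropy. Both are painted as
# piecewise-constant maps over beat regions so they align sample-by-sample
# with the signal and the DNN feature maps.

#' Feature extraction configuration
#'
#' @param context_len Context window for the representative normal RR
#'   interval, in RR intervals (the current interval sits at the middle).
#' @param scale_s Scale applied to the relative RR interval so the feature is
#'   not dwarfed by the learned channels.
#' @param sampen_m Sample-entropy template length.
#' @param sampen_r Sample-entropy match threshold (absolute, on the
#'   median-normalized RR series).
#' @param entropy_window Sliding window for the entropy map, in RR intervals.
#' @param sampen_cap Finite value returned when the entropy is undefined
#'   (no template matches); `NULL` caps at `log(P + 1)` where `P` is the
#'   number of template pairs in the window.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(context_len = 60, scale_s = 10, sampen_m = 1,
                           sampen_r = 0.05, entropy_window = 60,
                           sampen_cap = NULL) {
  stopifnot(context_len >= 2, sampen_r > 0, entropy_window > sampen_m + 1)
  structure(list(context_len = as.integer(context_len), scale_s = scale_s,
                 sampen_m = as.integer(sampen_m), sampen_r = sampen_r,
                 entropy_window = as.integer(entropy_window),
                 sampen_cap = sampen_cap),
            class = "feature_config")
}

#' Construct an R-peak set
#'
#' @param indices Strictly increasing 1-based sample indices of R peaks.
#' @param rate Sampling rate, Hz.
#' @return A list of class `rpeak_set` with `indices`, `rate` and the derived
#'   RR intervals in seconds (`rr`, one fewer than the peaks).
#' @export
rpeak_set <- function(indices, rate) {
  indices <- as.integer(indices)
  if (length(indices) > 1L && any(diff(indices) <= 0L)) {
    stop("R-peak indices must be strictly increasing")
  }
  stopifnot(rate > 0)
  structure(list(indices = indices, rate = as.numeric(rate),
                 rr = diff(indices) / rate),
            class = "rpeak_set")
}

#' Detect R peaks with a classical energy detector
#'
#' Band-limits the signal to the QRS band (5-18 Hz), squares it, integrates
#' over a 150 ms window, and applies an adaptive threshold with a 200 ms
#' refractory period; each detection is refined to the local absolute-signal
#' maximum. Intended as a fallback: when ground-truth beat annotations exist,
#' callers should use those positions instead.
#'
#' @param samples Preprocessed amplitude vector.
#' @param rate Sampling rate, Hz.
#' @return An [rpeak_set()]; empty (with a warning) for signals under 2 s.
#' @export
detect_rpeaks <- function(samples, rate) {
  n <- length(samples)
  if (n < 2 * rate) {
    warning("signal shorter than 2 s; no R peaks detected")
    return(rpeak_set(integer(), rate))
  }
  bf <- signal::butter(2, c(5, 18) / (rate / 2), type = "pass")
  qrs <- as.numeric(signal::filtfilt(bf, samples))
  energy <- qrs^2
  w <- max(1L, round(0.15 * rate))
  cs <- cumsum(c(0, energy))
  i <- seq_len(n)
  lo <- pmax(i - w %/% 2L, 1L)
  hi <- pmin(i + w %/% 2L, n)
  integ <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)

  thr <- 0.3 * mean(integ[integ >= stats::quantile(integ, 0.75)])
  above <- integ > thr
  refractory <- round(0.2 * rate)
  peaks <- integer()
  run_start <- NA_integer_
  for (k in seq_len(n)) {
    if (above[k] && is.na(run_start)) run_start <- k
    if ((!above[k] || k == n) && !is.na(run_start)) {
      run_end <- if (above[k]) k else k - 1L
      seg <- run_start:run_end
      cand <- seg[which.max(integ[seg])]
      # refine to the sharpest deflection of the band-limited signal nearby
      a <- max(1L, cand - w); b <- min(n, cand + w)
      cand <- (a:b)[which.max(abs(qrs[a:b]))]
      if (!length(peaks) || cand - peaks[length(peaks)] >= refractory) {
        peaks <- c(peaks, cand)
      } else if (integ[cand] > integ[peaks[length(peaks)]]) {
        peaks[length(peaks)] <- cand
      }
      run_start <- NA_integer_
    }
  }
  rpeak_set(sort(unique(peaks)), rate)
}

#' Partition a signal into beat regions
#'
#' The region of a heartbeat spans from the midpoint of its preceding RR
#' interval to the midpoint of its succeeding RR interval; the first region
#' starts at the first sample and the last ends at the final sample. Regions
#' are half-open `[start, end)` on 1-based indices and partition the signal.
#'
#' @param rpeaks An [rpeak_set()] with at least one peak.
#' @param n_samples Signal length.
#' @return A data.frame with columns `start` and `end` (one row per beat), or
#'   a single flagged no-beat region when there are no peaks.
#' @export
beat_regions <- function(rpeaks, n_samples) {
  p <- rpeaks$indices
  if (!length(p)) {
    out <- data.frame(start = 1L, end = n_samples + 1L)
    attr(out, "no_beats") <- TRUE
    return(out)
  }
  # interior boundary between beats i and i+1 at floor((p_i + p_{i+1}) / 2),
  # computed on 0-based positions to match the usual convention
  interior <- as.integer(floor(((p[-length(p)] - 1L) + (p[-1L] - 1L)) / 2)) + 1L
  starts <- c(1L, interior)
  ends <- c(interior, n_samples + 1L)
  data.frame(start = starts, end = ends)
}

#' Relative RR interval feature map
#'
#' For the beat owning RR interval `I_A` (the interval ending at its R peak),
#' the feature is `s * (I_N - I_A) / I_N`, where `I_N` is the mean of up to
#' `context_len` RR intervals in a window centered on the current interval
#' (clamped to the recording bounds; all intervals are used when fewer exist).
#' The value is positive when the current interval is shorter than its
#' context — the signature of a premature beat — and is painted over the
#' beat's region. The first beat, which owns no RR interval, inherits the
#' second beat's value.
#'
#' @param rpeaks An [rpeak_set()].
#' @param n_samples Signal length.
#' @param cfg A [feature_config()].
#' @return A numeric vector of length `n_samples`.
#' @export
relative_rr_map <- function(rpeaks, n_samples, cfg = feature_config()) {
  rr <- rpeaks$rr
  if (length(rr) < 1L) {
    warning("fewer than 2 R peaks; relative RR map is all zero")
    return(numeric(n_samples))
  }
  k <- length(rr)
  vals_rr <- vapply(seq_len(k), function(j) {
    win <- context_window(j, k, cfg$context_len)
    i_n <- mean(rr[win])
    cfg$scale_s * (i_n - rr[j]) / i_n
  }, numeric(1))
  beat_vals <- c(vals_rr[1L], vals_rr)  # beat i owns RR i-1; first inherits
  paint_regions(beat_regions(rpeaks, n_samples), beat_vals, n_samples)
}

# Window of up to `len` indices centered on j (j at position len/2 + 1),
# clamped to [1, k] while preserving the width where possible.
context_window <- function(j, k, len) {
  if (k <= len) return(seq_len(k))
  half_lo <- len %/% 2L
  lo <- j - half_lo
  hi <- lo + len - 1L
  if (lo < 1L) { lo <- 1L; hi <- len }
  if (hi > k) { hi <- k; lo <- k - len + 1L }
  lo:hi
}

paint_regions <- function(regions, values, n_samples) {
  out <- numeric(n_samples)
  for (i in seq_len(nrow(regions))) {
    a <- regions$start[i]; b <- regions$end[i] - 1L
    if (b >= a) out[a:b] <- values[i]
  }
  out
}

#' Sample entropy (SampEn)
#'
#' The negative natural log of the conditional probability that two distinct
#' templates of length `m + 1` match (Chebyshev distance <= `r`) given that
#' their first `m` points match. Returns 0 for a constant series; when no
#' matches exist the value is capped at `cap` (default `log(P + 1)` with `P`
#' the number of template pairs) so downstream maps stay finite.
#'
#' @param x Numeric series (length >= m + 2).
#' @param m Template length.
#' @param r Match threshold.
#' @param cap Cap for the undefined/no-match case; `NULL` for the default.
#' @return The entropy value, or `NA` for a too-short series.
#' @export
sampen <- function(x, m = 1L, r = 0.05, cap = NULL) {
  n <- length(x)
  if (n < m + 2L) return(NA_real_)
  # standard convention: both template lengths use the n - m starting
  # positions, so a constant series gives A = B and entropy 0
  count_matches <- function(len) {
    n_t <- n - m
    d <- matrix(0, n_t, n_t)
    for (off in 0:(len - 1L)) {
      seg <- x[(1L + off):(n_t + off)]
      d <- pmax(d, abs(outer(seg, seg, "-")))
    }
    (sum(d <= r) - n_t) / 2
  }
  b <- count_matches(m)
  a <- count_matches(m + 1L)
  if (is.null(cap)) {
    p_pairs <- (n - m - 1L) * (n - m) / 2
    cap <- log(p_pairs + 1)
  }
  if (b == 0 || a == 0) return(cap)
  min(-log(a / b), cap)
}

#' RR entropy feature map
#'
#' The RR series is divided by its median, then sample entropy is computed in
#' sliding windows of `entropy_window` RR intervals (all intervals when fewer
#' exist). Each window's value is painted on the region of the window's
#' central heartbeat; samples left unpainted at the record edges take the
#' value of their nearest painted neighbor.
#'
#' @inheritParams relative_rr_map
#' @return A numeric vector of length `n_samples`.
#' @export
rr_entropy_map <- function(rpeaks, n_samples, cfg = feature_config()) {
  rr <- rpeaks$rr
  if (length(rr) < 1L) {
    warning("fewer than 2 R peaks; RR entropy map is all zero")
    return(numeric(n_samples))
  }
  rr_norm <- rr / stats::median(rr)
  k <- length(rr)
  w <- cfg$entropy_window
  regions <- beat_regions(rpeaks, n_samples)
  n_beats <- nrow(regions)
  beat_vals <- rep(NA_real_, n_beats)
  if (k <= w) {
    e <- sampen(rr_norm, cfg$sampen_m, cfg$sampen_r, cfg$sampen_cap)
    if (is.na(e)) e <- 0
    beat_vals[] <- e
  } else {
    half <- w %/% 2L
    for (start in seq_len(k - w + 1L)) {
      central_rr <- start + half           # 0-based index `half` within window
      central_beat <- central_rr + 1L      # beat owning that RR interval
      beat_vals[central_beat] <-
        sampen(rr_norm[start:(start + w - 1L)], cfg$sampen_m, cfg$sampen_r,
               cfg$sampen_cap)
    }
    beat_vals <- fill_nearest(beat_vals)
  }
  paint_regions(regions, beat_vals, n_samples)
}

fill_nearest <- function(v) {
  idx <- which(!is.na(v))
  if (!length(idx)) return(ifelse(is.na(v), 0, v))
  nearest <- idx[pmax(1L, pmin(length(idx),
    findInterval(seq_along(v), idx + 0.5) +
      ifelse(seq_along(v) %in% idx, 0L, 1L)))]
  # choose the closer of the painted neighbors on either side
  left <- idx[pmax(1L, findInterval(seq_along(v), idx))]
  right <- idx[pmin(length(idx), findInterval(seq_along(v), idx) + 1L)]
  pick <- ifelse(abs(seq_along(v) - left) <= abs(right - seq_along(v)), left, right)
  v[is.na(v)] <- v[pick[is.na(v)]]
  v
}

#' Compute both knowledge feature maps for a record
#'
#' Uses annotated beat positions when available (every annotated beat,
#' including excluded F/Q beats, anchors the RR series), falling back to
#' [detect_rpeaks()] otherwise. Stores the maps and the R-peak set on the
#' record.
#'
#' @param record A preprocessed [ecg_record()].
#' @param cfg A [feature_config()].
#' @return The record with `rpeaks` and a 2-row `features` matrix attached
#'   (rows: relative RR, RR entropy).
#' @export
featurize_record <- function(record, cfg = feature_config()) {
  n <- length(record$samples)
  rp <- if (!is.null(record$beats) && nrow(record$beats) > 0L) {
    rpeak_set(record$beats$pos, record$sampling_rate)
  } else {
    detect_rpeaks(record$samples, record$sampling_rate)
  }
  record$rpeaks <- rp
  rel <- if (length(rp$indices) >= 2L) relative_rr_map(rp, n, cfg) else numeric(n)
  ent <- if (length(rp$indices) >= 2L) rr_entropy_map(rp, n, cfg) else numeric(n)
  record$features <- rbind(rel_rr = rel, rr_entropy = ent)
  record
}
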