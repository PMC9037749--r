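# Shared fixture builders; everything is generated in code at test time.

# A bare record with evenly spaced synthetic peaks (no morphology).
toy_record <- function(n = 500, rate = 125, peaks = NULL, classes = NULL) {
  x <- sin(2 * pi * seq_len(n) / 40)
  beats <- if (!is.null(peaks)) {
    map_beat_symbols(beat_annotation(peaks, classes %||% rep("N", length(peaks))))
  } else NULL
  ecg_record("toy", x, rate, beats = beats)
}

# Brute-force SampEn: explicit double loop over all template pairs (both
# lengths over the first n - m starting positions, the standard convention).
sampen_bruteforce <- function(x, m, r, cap = NULL) {
  n <- length(x)
  count <- function(len) {
    n_t <- n - m
    total <- 0L
    for (i in seq_len(n_t - 1L)) {
      for (j in (i + 1L):n_t) {
        d <- max(abs(x[i:(i + len - 1L)] - x[j:(j + len - 1L)]))
        if (d <= r) total <- total + 1L
      }
    }
    total
  }
  b <- count(m)
  a <- count(m + 1L)
  if (is.null(cap)) cap <- log((n - m - 1L) * (n - m) / 2 + 1)
  if (a == 0L || b == 0L) return(cap)
  min(-log(a / b), cap)
}

# Brute-force relative-RR values per beat: explicit window enumeration.
relative_rr_bruteforce <- function(rr, context_len = 60, s = 10) {
  k <- length(rr)
  vapply(seq_len(k), function(j) {
    if (k <= context_len) {
      win <- seq_len(k)
    } else {
      lo <- j - context_len %/% 2
      hi <- lo + context_len - 1
      if (lo < 1) { lo <- 1; hi <- context_len }
      if (hi > k) { hi <- k; lo <- k - context_len + 1 }
      win <- lo:hi
    }
    i_n <- mean(rr[win])
    s * (i_n - rr[j]) / i_n
  }, numeric(1))
}

# Brute-force average precision: explicit threshold sweep per its step-wise
# definition.
ap_bruteforce <- function(scores, truth) {
  truth <- as.integer(as.logical(truth))
  n_pos <- sum(truth)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  sen_prev <- 0
  ap <- 0
  for (th in thresholds) {
    pred <- scores >= th
    sen <- sum(pred & truth == 1L) / n_pos
    ppr <- sum(pred & truth == 1L) / sum(pred)
    ap <- ap + (sen - sen_prev) * ppr
    sen_prev <- sen
  }
  ap
}

# Fully prepared tiny synthetic corpus for model-level tests.
prepared_corpus <- function(n, seed) {
  prepare_records(generate_dataset(n, seed = seed)$records)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
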