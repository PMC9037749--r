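# Peaks in these tests are 1-based sample indices; the midpoint rule is
# computed on 0-based positions, matching floor((p_i + p_{i+1}) / 2).

test_that("beat regions partition the signal with midpoint boundaries", {
  rp <- rpeak_set(c(101, 201, 301), 125)
  reg <- beat_regions(rp, 400)
  expect_equal(reg$start, c(1L, 151L, 251L))
  expect_equal(reg$end, c(151L, 251L, 401L))
  # partition: contiguous, covers [1, n]
  expect_equal(reg$start[-1], reg$end[-nrow(reg)])

  one <- beat_regions(rpeak_set(200, 125), 400)
  expect_equal(c(one$start, one$end), c(1L, 401L))

  rp2 <- rpeak_set(c(1, 11), 125)
  reg2 <- beat_regions(rp2, 20)
  expect_equal(reg2$start, c(1L, 6L))
  expect_equal(reg2$end, c(6L, 21L))

  none <- beat_regions(rpeak_set(integer(), 125), 50)
  expect_true(isTRUE(attr(none, "no_beats")))
})

test_that("relative RR map matches direct substitution and is piecewise constant", {
  # all RR equal: identically zero
  rp <- rpeak_set(seq(1, 1001, by = 100), 125)
  expect_equal(relative_rr_map(rp, 1100), numeric(1100))

  # context mean 0.8 s, current 0.4 s, s = 10 -> 10 * (0.8 - 0.4) / 0.8 = 5
  # with a short context so the mean is exactly 0.8
  rate <- 125
  peaks <- cumsum(c(1, rep(0.8 * rate, 10), 0.4 * rate, rep(0.8 * rate, 10)))
  rp2 <- rpeak_set(peaks, rate)
  cfg <- feature_config(context_len = 60)
  m <- relative_rr_map(rp2, max(peaks) + 50, cfg)
  rr <- diff(peaks) / rate
  i_n <- mean(rr)  # 21 intervals < context_len: all used
  short_beat <- 12L  # beat owning the 0.4 s interval
  reg <- beat_regions(rp2, max(peaks) + 50)
  mid <- (reg$start[short_beat] + reg$end[short_beat]) %/% 2
  expect_equal(m[mid], 10 * (i_n - 0.4) / i_n, tolerance = 1e-12)
  # piecewise constant on regions
  for (b in c(3L, short_beat)) {
    vals <- m[reg$start[b]:(reg$end[b] - 1L)]
    expect_equal(max(vals) - min(vals), 0)
  }
  # first beat inherits the second beat's value
  expect_equal(m[1], m[reg$start[2]])
})

test_that("relative RR map agrees with a windowed-mean oracle beyond the context", {
  rate <- 125
  set.seed(42)
  rr_true <- c(rep(0.8, 30), 1.2, rep(0.8, 31))  # 62 intervals > 60 context
  peaks <- cumsum(c(10, round(rr_true * rate)))
  rp <- rpeak_set(peaks, rate)
  n <- max(peaks) + 10
  m <- relative_rr_map(rp, n, feature_config())
  oracle <- relative_rr_bruteforce(diff(peaks) / rate, 60, 10)
  reg <- beat_regions(rp, n)
  for (j in seq_along(oracle)) {           # beat j + 1 owns interval j
    expect_equal(m[reg$start[j + 1L]], oracle[j], tolerance = 1e-12)
  }
})

test_that("relative RR is scale invariant and signs premature beats positive", {
  rate <- 125
  rr <- c(rep(0.8, 10), 0.56, rep(0.8, 10))  # sample-exact at both scales
  p1 <- cumsum(c(1, round(rr * rate)))
  p2 <- cumsum(c(1, round(2 * rr * rate)))  # uniform time rescaling
  m1 <- relative_rr_map(rpeak_set(p1, rate), max(p1) + 5)
  m2 <- relative_rr_map(rpeak_set(p2, rate), max(p2) + 5)
  r1 <- beat_regions(rpeak_set(p1, rate), max(p1) + 5)
  r2 <- beat_regions(rpeak_set(p2, rate), max(p2) + 5)
  expect_equal(m1[r1$start[12]], m2[r2$start[12]], tolerance = 1e-9)
  expect_gt(m1[r1$start[12]], 0)   # short RR -> positive
  expect_lt(m1[r1$start[13]], 0)   # following long-ish context flips sign
})

test_that("sample entropy matches brute-force pair enumeration", {
  expect_equal(sampen(rep(1, 20), 1, 0.05), 0)
  x <- c(1.0, 1.1, 1.0, 1.1, 1.0, 1.1)
  expect_equal(sampen(x, 1, 0.05), sampen_bruteforce(x, 1, 0.05))
  # strictly monotone with steps > r: no matches, capped
  mono <- seq(0, 2, by = 0.1)
  expect_equal(sampen(mono, 1, 0.05),
               log((length(mono) - 2) * (length(mono) - 1) / 2 + 1))
  set.seed(7)
  for (i in 1:20) {
    n <- sample(10:80, 1)
    y <- rnorm(n, sd = sample(c(0.02, 0.1, 1), 1))
    for (m in c(1L, 2L)) {
      expect_identical(sampen(y, m, 0.05), sampen_bruteforce(y, m, 0.05))
    }
  }
  expect_true(is.na(sampen(c(1, 2), 1, 0.05)))
})

test_that("RR entropy map paints windows onto central beats", {
  rate <- 125
  # perfectly regular: zero everywhere
  rp <- rpeak_set(seq(1, 2401, by = 100), rate)
  expect_equal(rr_entropy_map(rp, 2500), numeric(2500))

  # fewer intervals than the window: one value painted everywhere
  rr10 <- c(0.8, 0.75, 0.85, 0.8, 0.7, 0.9, 0.8, 0.78, 0.82)
  rp10 <- rpeak_set(cumsum(c(1, round(rr10 * rate))), rate)
  m10 <- rr_entropy_map(rp10, 1000)
  expect_equal(length(unique(m10)), 1L)
  e <- sampen(rp10$rr / median(rp10$rr), 1, 0.05)
  expect_equal(unique(m10), e)

  # long alternating-RR bigeminy with physiological jitter: strictly positive
  # everywhere (a perfectly deterministic alternation would give zero), and
  # each painted value equals the brute-force SampEn of its window
  set.seed(2)
  rr_alt <- rep(c(0.5, 1.1), 45) + round(rnorm(90, sd = 0.02), 3)
  peaks <- cumsum(c(1, round(rr_alt * rate)))
  rpb <- rpeak_set(peaks, rate)
  n <- max(peaks) + 10
  mb <- rr_entropy_map(rpb, n)
  expect_true(all(mb > 0))
  rrn <- rpb$rr / median(rpb$rr)
  reg <- beat_regions(rpb, n)
  k <- length(rrn)
  for (start in c(1L, 5L, k - 59L)) {
    central_beat <- start + 30L + 1L
    expect_equal(mb[reg$start[central_beat]],
                 sampen_bruteforce(rrn[start:(start + 59L)], 1, 0.05))
  }
})

test_that("feature maps align with the signal and zero-fill degenerate input", {
  r <- prepare_records(list(generate_record(synth_spec(seed = 3))))[[1]]
  expect_equal(ncol(r$features), length(r$samples))
  expect_warning(m <- relative_rr_map(rpeak_set(100, 125), 500), "fewer")
  expect_equal(m, numeric(500))
})

test_that("the energy detector finds synthetic R peaks within tolerance", {
  r <- generate_record(synth_spec(seed = 21, noise_sd = 0.02, wander_amp = 0.05))
  pre <- preprocess_record(r)
  det <- detect_rpeaks(pre$samples, pre$sampling_rate)
  truth <- pre$beats$pos
  expect_gte(length(det$indices), length(truth) - 1L)
  matched <- match_beats(det$indices, truth, 125)
  expect_gte(mean(!is.na(matched)), 0.95)
  offs <- abs(det$indices[matched[!is.na(matched)]] - truth[!is.na(matched)])
  expect_lte(stats::median(offs), 3)
  expect_warning(e <- detect_rpeaks(rnorm(100), 125), "shorter")
  expect_length(e$indices, 0L)
  # flat signal: no peaks
  expect_length(detect_rpeaks(rep(0, 1000), 125)$indices, 0L)
})
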