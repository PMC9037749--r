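test_that("baseline removal subtracts the centered moving average", {
  expect_equal(remove_baseline(rep(5, 100), 125, 1), rep(0, 100))
  # interior of a linear ramp is its own symmetric-window average
  ramp <- seq(0, 1, length.out = 400)
  out <- remove_baseline(ramp, 125, 1)
  expect_lt(max(abs(out[100:300])), 1e-10)
  # unit impulse: direct convolution oracle
  x <- numeric(251); x[126] <- 1
  w <- round(1 * 125)
  half_lo <- (w - 1) %/% 2; half_hi <- w - 1 - half_lo
  oracle <- vapply(seq_along(x), function(i) {
    lo <- max(i - half_lo, 1); hi <- min(i + half_hi, length(x))
    x[i] - mean(x[lo:hi])
  }, numeric(1))
  expect_equal(remove_baseline(x, 125, 1), oracle)
  expect_error(remove_baseline(numeric(), 125, 1), "empty")
})

test_that("band-pass attenuates out-of-band tones and preserves the passband", {
  rate <- 125
  t <- seq_len(2000) / rate
  amp_at <- function(x, f) {
    sp <- abs(fft(x))
    sp[round(f * length(x) / rate) + 1L]
  }
  tone50 <- sin(2 * pi * 50 * t)
  out50 <- bandpass(tone50, rate, 0.1, 30)
  expect_lt(amp_at(out50, 50), amp_at(tone50, 50) / 20)
  tone10 <- sin(2 * pi * 10 * t)
  out10 <- bandpass(tone10, rate, 0.1, 30)
  expect_equal(amp_at(out10, 10) / amp_at(tone10, 10), 1, tolerance = 0.1)
  expect_equal(bandpass(numeric(100), rate), numeric(100))
  expect_error(bandpass(tone10, rate = 50, high = 30), "twice")
})

test_that("zero-phase filtering leaves peak positions in place", {
  r <- generate_record(synth_spec(seed = 9, noise_sd = 0, wander_amp = 0))
  filt <- bandpass(r$samples, 125, 0.1, 30)
  for (p in r$beats$pos[2:5]) {
    win <- (p - 4):(p + 4)
    expect_lte(abs(win[which.max(filt[win])] - p), 1)
  }
})

test_that("resampling honors the tolerance exemption and length arithmetic", {
  x500 <- sin(2 * pi * 5 * seq_len(5000) / 500)
  rs <- resample_to(x500, 500, 125, 3)
  expect_equal(length(rs$samples), 1250)
  expect_equal(rs$rate, 125)
  # 128 Hz is close enough to 125: untouched
  x128 <- sin(seq_len(1280) / 7)
  rs128 <- resample_to(x128, 128, 125, 3)
  expect_identical(rs128$samples, x128)
  expect_equal(rs128$rate, 128)
  expect_identical(resample_to(x128, 125, 125, 3)$samples, x128)
  # content preserved: output sample i sits on the original time grid
  expected <- sin(2 * pi * 5 * seq(1, 5000, by = 4) / 500)
  expect_equal(rs$samples, expected, tolerance = 1e-9)
})

test_that("amplitude normalization standardizes and is affine invariant", {
  expect_equal(normalize_signal(c(1, 3)), c(-1, 1))
  x <- rnorm(500)
  z <- normalize_signal(x)
  expect_lt(abs(mean(z)), 1e-6)
  expect_lt(abs(mean(z^2) - 1), 1e-6)
  expect_equal(normalize_signal(3 * x + 7), z)
  expect_warning(zc <- normalize_signal(rep(2, 10)), "constant")
  expect_equal(zc, rep(0, 10))
})

test_that("label complementation follows the co-occurrence rule", {
  expect_setequal(complement_labels("S"), c("S", "N"))
  expect_setequal(complement_labels(c("V", "IVR")), c("V", "IVR"))
  expect_equal(complement_labels("N"), "N")
  expect_equal(complement_labels(character()), character())
  # idempotence
  expect_setequal(complement_labels(complement_labels("V")), c("V", "N"))
})

test_that("padding and truncation hit the exact target length", {
  r6 <- ecg_record("p1", rnorm(750), 125)  # 6 s
  p <- pad_or_truncate(r6, 20)
  expect_length(p$samples, 2500)
  expect_equal(p$samples[751:2500], rep(0, 1750))
  expect_equal(p$valid_n, 750)

  r30 <- ecg_record("p2", rnorm(3750), 125,
                    beats = beat_annotation(c(100, 3000), c("N", "N")))
  p30 <- pad_or_truncate(r30, 20)
  expect_length(p30$samples, 2500)
  expect_equal(p30$samples, r30$samples[1:2500])
  expect_equal(p30$beats$pos, 100L)  # beat beyond the cut dropped
  expect_equal(p30$valid_n, 2500)

  r20 <- ecg_record("p3", rnorm(2500), 125)
  expect_equal(pad_or_truncate(r20, 20)$samples, r20$samples)
})

test_that("repeated preprocessing is a small perturbation that keeps R peaks", {
  r <- generate_record(synth_spec(seed = 5, rhythm = "mixed", p_s = 0.08,
                                  p_v = 0.08))
  p1 <- preprocess_record(r)
  p2 <- preprocess_record(p1)
  rms_first <- sqrt(mean((p1$samples - normalize_signal(r$samples))^2))
  rms_second <- sqrt(mean((p2$samples - p1$samples)^2))
  expect_lt(rms_second, 0.5 * rms_first)
  # R peaks stay the local maxima they were (zero-phase pipeline)
  for (p in p1$beats$pos[2:6]) {
    win <- (p - 4):(p + 4)
    expect_lte(abs(win[which.max(p2$samples[win])] - p), 1)
  }
  expect_identical(p2$label_set, p1$label_set)  # complementation idempotent
})

test_that("preprocessing rescales beat positions with the sampling rate", {
  n <- 5000
  x <- sin(2 * pi * 8 * seq_len(n) / 500) * exp(-((seq_len(n) %% 400) / 40)^2)
  r <- ecg_record("rs", x, 500, beats = beat_annotation(c(1000, 2000), c("N", "V")))
  p <- preprocess_record(r)
  expect_equal(p$sampling_rate, 125)
  expect_equal(p$beats$pos, c(250L, 500L), tolerance = 1)
})
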