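test_that("beat templates encode the class morphologies", {
  n <- beat_template("N")
  s <- beat_template("S")
  v <- beat_template("V")
  # width of the deflection complex around the R peak (T wave excluded)
  qrs_width <- function(tmpl) {
    win <- (tmpl$center - round(0.12 * 125)):(tmpl$center + round(0.12 * 125))
    sum(abs(tmpl$wave[win]) > 0.25)
  }
  expect_gt(qrs_width(v), qrs_width(n))
  expect_gt(qrs_width(v), 0.140 * 125)  # wide QRS over 140 ms
  expect_lt(qrs_width(n), 0.100 * 125)  # narrow QRS under 100 ms
  for (tmpl in list(n, s, v)) expect_equal(max(abs(tmpl$wave)), 1)
  # deterministic (no RNG involvement)
  expect_identical(beat_template("V"), beat_template("V"))
  # N has a P wave before the QRS, S does not
  p_window <- seq_len(n$center - round(0.1 * 125))
  expect_gt(max(n$wave[p_window]), 0.1)
  expect_lt(max(abs(s$wave[p_window])), 0.05)
})

test_that("record generation follows the rhythm grammar", {
  pure <- generate_record(synth_spec(seed = 4, rhythm = "sinus"))
  expect_true(all(pure$beats$class == "N"))
  expect_equal(pure$label_set, "N")

  big <- generate_record(synth_spec(seed = 4, rhythm = "bigeminy_V"))
  expect_gte(sum(big$beats$class == "V"), 8L)
  expect_setequal(big$label_set, c("N", "V"))

  expect_identical(generate_record(synth_spec(seed = 123, rhythm = "mixed",
                                              p_s = 0.1, p_v = 0.1)),
                   generate_record(synth_spec(seed = 123, rhythm = "mixed",
                                              p_s = 0.1, p_v = 0.1)))
  expect_error(synth_spec(p_s = 1.5), "0, 1")
  expect_error(synth_spec(base_rr = 0.2), "0.25")
})

test_that("ectopic pause semantics distinguish S from V", {
  set.seed(0)
  spec_v <- synth_spec(seed = 15, rhythm = "mixed", p_v = 0.15, rr_jitter = 0.01)
  r <- generate_record(spec_v)
  rr <- diff(r$beats$pos) / 125
  v_idx <- which(r$beats$class == "V")
  v_idx <- v_idx[v_idx > 1 & v_idx < nrow(r$beats)]
  for (i in v_idx) {
    # compensatory: flanking intervals sum to about two sinus cycles
    expect_equal(rr[i - 1] + rr[i], 2 * 0.8, tolerance = 0.06)
    expect_lt(rr[i - 1], 0.8 * 0.85)  # premature
  }
  spec_s <- synth_spec(seed = 16, rhythm = "mixed", p_s = 0.15, rr_jitter = 0.01)
  rs <- generate_record(spec_s)
  rrs <- diff(rs$beats$pos) / 125
  s_idx <- which(rs$beats$class == "S")
  s_idx <- s_idx[s_idx > 1 & s_idx < nrow(rs$beats)]
  expect_gt(length(s_idx), 0)
  for (i in s_idx) {
    expect_lt(rrs[i - 1], 0.8 * 0.85)              # premature
    expect_lt(rrs[i - 1] + rrs[i], 2 * 0.8 - 0.05) # non-compensatory
  }
})

test_that("dataset generation hits the category mix exactly and reproducibly", {
  ds <- generate_dataset(40, c(0.2, 0.2, 0.1, 0.5), seed = 6)
  expect_equal(unname(table(ds$manifest$category)[c("s_only", "v_only", "both",
                                                    "neither")]),
               c(8L, 8L, 4L, 20L), ignore_attr = TRUE)
  has <- function(r, cl) cl %in% r$beats$class
  for (i in seq_len(40)) {
    r <- ds$records[[i]]
    cat_i <- ds$manifest$category[i]
    expect_equal(has(r, "S"), cat_i %in% c("s_only", "both"))
    expect_equal(has(r, "V"), cat_i %in% c("v_only", "both"))
  }
  ds2 <- generate_dataset(40, c(0.2, 0.2, 0.1, 0.5), seed = 6)
  expect_identical(ds$records[[1]]$samples, ds2$records[[1]]$samples)
  # different master seeds give different corpora
  ds3 <- generate_dataset(40, c(0.2, 0.2, 0.1, 0.5), seed = 7)
  expect_false(identical(ds$records[[1]]$samples, ds3$records[[1]]$samples))
  expect_error(generate_dataset(10, c(0, 0, 0, 0)), "mix")
})

test_that("generated truth round-trips through label derivation", {
  ds <- generate_dataset(12, seed = 44)
  for (r in ds$records) {
    derived <- derive_record_labels(r$beats)
    expect_true(all(derived %in% r$label_set))
    expect_setequal(complement_labels(derived), r$label_set)
  }
})

test_that("knowledge features respond to the generated rhythms as designed", {
  recs <- prepare_records(generate_dataset(10, c(0.3, 0.3, 0, 0.4),
                                           seed = 70)$records)
  rel_vals <- list(ect = numeric(), sinus = numeric())
  for (r in recs) {
    ect <- which(r$beats$class %in% c("S", "V"))
    ect <- ect[ect > 1]
    sin_b <- which(r$beats$class == "N")
    rel_vals$ect <- c(rel_vals$ect, r$features[1, r$beats$pos[ect]])
    rel_vals$sinus <- c(rel_vals$sinus, r$features[1, r$beats$pos[sin_b]])
  }
  # premature beats carry clearly positive relative-RR values
  expect_gt(mean(rel_vals$ect > 1), 0.95)
  expect_lt(abs(median(rel_vals$sinus)), 1)

  ent_of <- function(rhythm, seed) {
    r <- prepare_records(list(generate_record(
      synth_spec(seed = seed, rhythm = rhythm,
                 p_s = ifelse(rhythm == "mixed", 0.1, 0)))))[[1]]
    median(r$features[2, ])
  }
  expect_gt(ent_of("af_like", 3), ent_of("sinus", 3))
  expect_gt(ent_of("bigeminy_V", 3), ent_of("sinus", 3))
})

test_that("a synthetic corpus writes and reads back through the columnar format", {
  ds <- generate_dataset(3, seed = 29)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  r0 <- ds$records[[1]]
  r1 <- read_record(file.path(dir, paste0(r0$record_id, ".ecg")))
  expect_equal(r1$samples, r0$samples, tolerance = 1e-9)
  expect_identical(r1$beats$pos, r0$beats$pos)
  expect_setequal(r1$label_set, r0$label_set)
})

test_that("the CLI synthesizes a corpus end to end", {
  dir <- withr::local_tempdir()
  weakbeat_cli(c("synth", "--n", "4", "--mix", "0.25,0.25,0,0.5", "--seed",
                 "5", "--out", dir))
  expect_length(list.files(dir, pattern = "\\.ecg$"), 4L)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
})
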