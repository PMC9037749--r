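test_that("weak loss matches the mean binary cross-entropy formula", {
  g <- c(N = 1 - 1e-9, S = 1 - 1e-9, V = 1 - 1e-9)
  expect_lt(weak_loss(g, c("N", "S", "V")), 1e-5)
  expect_equal(weak_loss(c(N = 0.5, S = 0.5, V = 0.5), "N"), log(2),
               tolerance = 1e-12)
  expect_equal(weak_loss(c(N = 0.9, S = 0.1, V = 0.2), "N"),
               -(log(0.9) + log(0.9) + log(0.8)) / 3, tolerance = 1e-12)
  expect_equal(weak_loss(c(N = 0.9, S = 0.1, V = 0.2), "N"), 0.1446,
               tolerance = 1e-3)
  # clamping keeps extreme scores finite
  expect_true(is.finite(weak_loss(c(N = 0, S = 1, V = 0.5), "N")))
  expect_gte(weak_loss(c(N = 0.3, S = 0.3, V = 0.3), c("N", "V")), 0)
})

test_that("weak loss gradient agrees with finite differences", {
  g <- c(N = 0.7, S = 0.2, V = 0.45)
  labels <- c("N", "V")
  an <- weakbeat:::weak_loss_grad(g, labels)
  eps <- 1e-6
  for (i in 1:3) {
    gp <- g; gp[i] <- gp[i] + eps
    gm <- g; gm[i] <- gm[i] - eps
    fd <- (weak_loss(gp, labels) - weak_loss(gm, labels)) / (2 * eps)
    expect_equal(an[i], fd, tolerance = 1e-5)
  }
})

test_that("record weights follow the ectopic-content rule", {
  expect_equal(sample_weight(c("S", "N")), 2)
  expect_equal(sample_weight(c("S", "V", "N")), 4)
  expect_equal(sample_weight("N"), 0.1)
  expect_equal(sample_weight(c("V", "N")), 2)
  expect_equal(sample_weight(character()), 0.1)
  expect_equal(sample_weight(c("S", "V")), 4)
})

test_that("supervised loss is the categorical cross-entropy at R peaks", {
  pm <- matrix(1e-9, 3, 100, dimnames = list(c("N", "S", "V"), NULL))
  beats <- map_beat_symbols(beat_annotation(c(20, 70), c("N", "V")))
  pm["N", 20] <- 1 - 1e-9
  pm["V", 70] <- 1 - 1e-9
  expect_lt(supervised_loss(pm, beats), 1e-6)

  unif <- matrix(1 / 3, 3, 100, dimnames = list(c("N", "S", "V"), NULL))
  expect_equal(supervised_loss(unif, beats), log(3), tolerance = 1e-12)

  pm2 <- unif
  pm2[, 20] <- c(0.7, 0.15, 0.15)
  pm2[, 70] <- c(0.5, 0.3, 0.2)
  expect_equal(supervised_loss(pm2, beats), -(log(0.7) + log(0.2)) / 2,
               tolerance = 1e-12)
  expect_equal(supervised_loss(pm2, beats), 0.9831, tolerance = 1e-4)

  excl <- map_beat_symbols(beat_annotation(c(20, 70), c("F", "Q")))
  expect_warning(l0 <- supervised_loss(unif, excl), "usable")
  expect_equal(l0, 0)
})

test_that("weighting with unit weights reduces to the unweighted mean loss", {
  set.seed(2)
  scores <- replicate(6, setNames(runif(3), c("N", "S", "V")), simplify = FALSE)
  labsets <- list("N", c("N", "S"), c("N", "V"), c("N", "S", "V"), "S",
                  character())
  unit <- c(ectopic_single = 1, ectopic_both = 1, none = 1)
  weighted <- mean(mapply(function(g, l) sample_weight(l, unit) * weak_loss(g, l),
                          scores, labsets))
  unweighted <- mean(mapply(weak_loss, scores, labsets))
  expect_equal(weighted, unweighted)
})

test_that("weak-loss gradients vanish at non-R-peak samples under MGMP", {
  # end-to-end masking: the derivative of the record loss with respect to
  # each local probability is zero away from the R peaks
  set.seed(6)
  n <- 300
  pm <- matrix(runif(3 * n), 3, dimnames = list(c("N", "S", "V"), NULL))
  pm <- sweep(pm, 2, colSums(pm), "/")
  peaks <- sort(sample(n, 8))
  labels <- c("N", "V")
  agg <- aggregation_config("MGMP")
  loss_of <- function(p) {
    weak_loss(aggregate_global(p, agg, rpeaks = peaks), labels)
  }
  base <- loss_of(pm)
  eps <- 1e-4
  non_peaks <- sample(setdiff(seq_len(n), peaks), 40)
  for (i in non_peaks) {
    p2 <- pm; p2[, i] <- p2[, i] + eps
    expect_identical(loss_of(p2), base)
  }
  # and at the selected peaks the gradient is non-zero for the argmax class
  W <- weakbeat:::aggregate_weights(pm, agg, rpeaks = peaks)
  dg <- weakbeat:::weak_loss_grad(aggregate_global(pm, agg, rpeaks = peaks),
                                  labels)
  dlocal <- dg * W
  expect_true(all(rowSums(dlocal != 0) == 1))
  expect_true(all(which(colSums(dlocal != 0) > 0) %in% peaks))
})

test_that("training is seeded, early-stops, and honors the epoch budget", {
  recs <- prepared_corpus(8, seed = 31)
  bb <- backbone_config(n_blocks = 2, kernels = 8)
  cfg <- train_config(seed = 17, max_epochs = 3, batch_size = 4)
  set.seed(17); m <- wb_model(bb)
  fit1 <- train_weak(m, recs[1:6], recs[7:8], cfg)
  set.seed(17); m2 <- wb_model(bb)
  fit2 <- train_weak(m2, recs[1:6], recs[7:8], cfg)
  expect_identical(fit1$model$params, fit2$model$params)
  expect_equal(nrow(fit1$history), 3L)

  # lr = 0: parameters never change, validation F1 constant, so with
  # patience 1 training stops right after the second epoch
  cfg0 <- train_config(seed = 17, lr = 0, patience = 1, max_epochs = 10,
                       batch_size = 4)
  fit0 <- train_weak(m, recs[1:6], recs[7:8], cfg0)
  expect_equal(nrow(fit0$history), 2L)
  expect_error(train_weak(m, list(), recs[7:8], cfg), "non-empty")
})

test_that("one epoch of weak training reduces the loss on a toy corpus", {
  recs <- prepared_corpus(12, seed = 77)
  set.seed(5)
  m <- wb_model(backbone_config(n_blocks = 2, kernels = 8))
  cfg <- train_config(seed = 5, max_epochs = 4, batch_size = 6)
  fit <- train_weak(m, recs[1:10], recs[11:12], cfg)
  expect_lt(fit$history$loss[4], fit$history$loss[1])
})

test_that("supervised pretraining fits separable synthetic beats", {
  recs <- prepared_corpus(16, seed = 55)
  set.seed(9)
  m <- wb_model()
  expect_identical(pretrain_supervised(m, recs, epochs = 0)$params, m$params)
  m2 <- pretrain_supervised(m, recs, epochs = 15,
                            train_config(seed = 9, batch_size = 8))
  rep <- evaluate_beats(m2, recs)
  # the wide-QRS class is morphologically separable and should be learned
  expect_gt(rep$classes$V$F1, 0.9)
  expect_gt(rep$classes$N$F1, 0.9)
})

test_that("two-stage training reduces to pure weak training without fine data", {
  recs <- prepared_corpus(10, seed = 91)
  bb <- backbone_config(n_blocks = 2, kernels = 8)
  cfg <- train_config(seed = 3, max_epochs = 2, batch_size = 4)
  set.seed(3); m <- wb_model(bb)
  fit_two <- two_stage_train(m, list(), recs[1:8], recs[9:10], cfg)
  set.seed(3); m2 <- wb_model(bb)
  cfg2 <- cfg; cfg2$seed <- NULL
  set.seed(cfg$seed)
  fit_weak <- train_weak(m2, recs[1:8], recs[9:10], cfg2)
  expect_identical(fit_two$model$params, fit_weak$model$params)
})
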