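# Training: weighted binary cross-entropy on record-level labels (weak
# supervision), categorical cross-entropy at R peaks (supervised
# pre-training), Adam optimization with early stopping on validation F1,
# and the two-stage strategy combining both.

#' Training configuration
#'
#' @param lr,beta1,beta2 Adam hyperparameters.
#' @param batch_size Records per optimization step.
#' @param patience Early-stopping patience: training stops when the mean
#'   validation F1 over the classes has not increased for this many epochs.
#' @param max_epochs Upper bound on weak-training epochs.
#' @param pretrain_epochs Fixed epoch budget of the supervised stage.
#' @param pretrain_batch_size Records per optimization step in the
#'   supervised stage; small by default because finely annotated sets are
#'   small and the stage must deliver enough optimizer updates to anchor
#'   the weak stage.
#' @param weights Record weights for the class-imbalance correction:
#'   `ectopic_single` (record labels contain exactly one of S, V),
#'   `ectopic_both` (both) and `none` (neither).
#' @param seed Integer seed consumed by every stochastic element
#'   (initialization is the caller's, shuffling and dropout are seeded here);
#'   `NULL` continues the current stream.
#' @param val_metric `"beat"` (argmax of local probabilities at annotated R
#'   peaks; the validation records must carry beat labels) or `"record"`
#'   (global scores thresholded at 0.5 against record label sets).
#' @param eps_clamp Clamp applied to aggregated scores before logarithms
#'   (global max pooling can emit exact 0 or 1).
#' @return A list of class `train_config`.
#' @export
train_config <- function(lr = 0.001, beta1 = 0.9, beta2 = 0.999,
                         batch_size = 16, patience = 10, max_epochs = 15,
                         pretrain_epochs = 10, pretrain_batch_size = 4,
                         weights = c(ectopic_single = 2, ectopic_both = 4,
                                     none = 0.1),
                         seed = NULL, val_metric = c("beat", "record"),
                         eps_clamp = 1e-7) {
  stopifnot(patience >= 1, all(weights > 0), batch_size >= 1, max_epochs >= 1)
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 pretrain_epochs = as.integer(pretrain_epochs),
                 pretrain_batch_size = as.integer(pretrain_batch_size),
                 weights = weights, seed = seed,
                 val_metric = match.arg(val_metric), eps_clamp = eps_clamp),
            class = "train_config")
}

#' Weak (record-level) loss: mean binary cross-entropy over classes
#'
#' `-(1/|C|) sum_c [t_c log f_c + (1 - t_c) log(1 - f_c)]` where `t_c`
#' indicates the presence of class `c` in the record's label set and `f_c`
#' is the aggregated global score, clamped away from 0/1.
#'
#' @param global Named per-class score vector (names over N, S, V).
#' @param labels Record-level label set.
#' @param eps Clamp width.
#' @return Non-negative scalar loss.
#' @export
weak_loss <- function(global, labels, eps = 1e-7) {
  cls <- names(global)
  if (is.null(cls)) cls <- AAMI_CLASSES[seq_along(global)]
  t <- as.numeric(cls %in% labels)
  f <- pmin(pmax(as.numeric(global), eps), 1 - eps)
  -mean(t * log(f) + (1 - t) * log(1 - f))
}

# d(weak_loss)/d(global), on the clamped scores.
weak_loss_grad <- function(global, labels, eps = 1e-7) {
  cls <- names(global)
  if (is.null(cls)) cls <- AAMI_CLASSES[seq_along(global)]
  t <- as.numeric(cls %in% labels)
  f <- pmin(pmax(as.numeric(global), eps), 1 - eps)
  g <- -(t / f - (1 - t) / (1 - f)) / length(f)
  # no gradient through the clamp
  g[(global <= eps & t == 0) | (global >= 1 - eps & t == 1)] <- 0
  g
}

#' Per-record loss weight for class imbalance
#'
#' Records whose label set contains both S and V get weight
#' `weights["ectopic_both"]`; exactly one of S, V gets
#' `weights["ectopic_single"]`; neither gets `weights["none"]`.
#'
#' @param labels Record-level label set.
#' @param weights Named weight vector, see [train_config()].
#' @return Scalar weight.
#' @export
sample_weight <- function(labels, weights = c(ectopic_single = 2,
                                              ectopic_both = 4, none = 0.1)) {
  n_ect <- sum(c("S", "V") %in% labels)
  if (n_ect == 2L) unname(weights["ectopic_both"])
  else if (n_ect == 1L) unname(weights["ectopic_single"])
  else unname(weights["none"])
}

#' Supervised loss: categorical cross-entropy at the R peaks
#'
#' `-(1/|R|) sum_{i in R} log p_{i, y_i}` over non-excluded annotated beats.
#'
#' @param local A `(classes x n)` local probability matrix.
#' @param beats A mapped [beat_annotation()].
#' @return Scalar loss; 0 with a warning when no usable beats exist.
#' @export
supervised_loss <- function(local, beats) {
  if (is.null(beats$class)) stop("beats must be mapped to AAMI classes")
  use <- !beats$excluded & beats$pos <= ncol(local)
  if (!any(use)) {
    warning("no usable beats for the supervised loss")
    return(0)
  }
  p <- local[cbind(match(beats$class[use], rownames(local)), beats$pos[use])]
  -mean(log(pmax(p, 1e-12)))
}

# ---------------------------------------------------------------------------
# Adam

adam_init <- function(params) {
  zeros <- lapply(params, function(p) array(0, dim = if (is.matrix(p)) dim(p) else length(p)))
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1, beta2, eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) + eps)
  }
  list(params = params, state = state)
}

# ---------------------------------------------------------------------------

# Predict local probabilities for a list of equal-length records in batches.
predict_records <- function(model, records, batch_size = 32L) {
  out <- vector("list", length(records))
  i <- 1L
  while (i <= length(records)) {
    j <- min(i + batch_size - 1L, length(records))
    ba <- batch_arrays(records[i:j])
    probs <- nn_forward_cpp(model$params, model$bn_state, ba$sig, ba$feats,
                            model$backbone$n_blocks, model$backbone$kernel_len,
                            model$backbone$pool)$probs
    for (b in seq_len(ba$B)) {
      pm <- probs[, ((b - 1L) * ba$L + 1L):(b * ba$L), drop = FALSE]
      rownames(pm) <- model$classes
      out[[i + b - 1L]] <- pm
    }
    i <- j + 1L
  }
  out
}

# Mean beat-level F1 over the classes on annotated records.
validation_f1 <- function(model, records, classes = AAMI_CLASSES) {
  probs <- predict_records(model, records)
  pred <- character()
  truth <- character()
  for (i in seq_along(records)) {
    r <- records[[i]]
    if (is.null(r$beats) || is.null(r$beats$class)) next
    use <- !r$beats$excluded & r$beats$pos <= ncol(probs[[i]])
    if (!any(use)) next
    pred <- c(pred, beat_decisions(probs[[i]], r$beats$pos[use]))
    truth <- c(truth, r$beats$class[use])
  }
  if (!length(truth)) return(0)
  mean(vapply(classes, function(cl) {
    class_rates(confusion_counts(pred, truth, cl))$F1
  }, numeric(1)))
}

validation_f1_record <- function(model, records, agg, classes = AAMI_CLASSES) {
  probs <- predict_records(model, records)
  score <- vapply(seq_along(records), function(i) {
    aggregate_global(probs[[i]], agg, rpeaks = records[[i]]$rpeaks,
                     valid_n = records[[i]]$valid_n)
  }, numeric(length(classes)))
  mean(vapply(seq_along(classes), function(ci) {
    pred_here <- ifelse(score[ci, ] >= 0.5, classes[ci], "-")
    truth_here <- ifelse(vapply(records, function(r) classes[ci] %in% r$label_set,
                                logical(1)), classes[ci], "-")
    class_rates(confusion_counts(pred_here, truth_here, classes[ci]))$F1
  }, numeric(1)))
}

#' Weakly supervised training on record-level labels
#'
#' Minimizes the weighted mean of the record-level binary cross-entropy
#' ([weak_loss()], weights from [sample_weight()]) with Adam. After every
#' epoch, the mean validation F1 over the classes is computed; training stops
#' when it has not improved for `patience` epochs (or at `max_epochs`), and
#' the best-epoch parameters are restored.
#'
#' @param model A [wb_model()].
#' @param train_records Featurized, padded records with (complemented)
#'   record-level label sets.
#' @param val_records Featurized, padded records with beat-level labels (for
#'   the default beat-level validation metric).
#' @param cfg A [train_config()].
#' @param agg An [aggregation_config()].
#' @param verbose Print per-epoch progress.
#' @return List with the trained `model` and a `history` data.frame
#'   (epoch, loss, val_f1).
#' @export
train_weak <- function(model, train_records, val_records,
                       cfg = train_config(), agg = aggregation_config(),
                       verbose = FALSE) {
  if (!length(train_records) || !length(val_records)) {
    stop("training and validation sets must be non-empty")
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  empty <- vapply(train_records, function(r) length(r$label_set) == 0L, logical(1))
  if (any(empty)) {
    warning(sum(empty), " training record(s) have an empty label set")
  }
  opt <- adam_init(model$params)
  best <- list(f1 = -Inf, params = model$params, bn = model$bn_state,
               epoch = 0L)
  history <- data.frame(epoch = integer(), loss = numeric(), val_f1 = numeric())

  for (epoch in seq_len(cfg$max_epochs)) {
    order_ <- sample(length(train_records))
    losses <- numeric()
    i <- 1L
    while (i <= length(order_)) {
      j <- min(i + cfg$batch_size - 1L, length(order_))
      batch <- train_records[order_[i:j]]
      ba <- batch_arrays(batch)
      loss_grad <- function(probs) {
        dprobs <- matrix(0, nrow(probs), ncol(probs))
        total <- 0
        for (b in seq_len(ba$B)) {
          cols <- ((b - 1L) * ba$L + 1L):(b * ba$L)
          pm <- probs[, cols, drop = FALSE]
          rownames(pm) <- model$classes
          r <- batch[[b]]
          g <- aggregate_global(pm, agg, rpeaks = r$rpeaks, valid_n = r$valid_n)
          w <- sample_weight(r$label_set, cfg$weights)
          total <- total + w * weak_loss(g, r$label_set, cfg$eps_clamp)
          dg <- w * weak_loss_grad(g, r$label_set, cfg$eps_clamp) / ba$B
          aw <- aggregate_weights(pm, agg, rpeaks = r$rpeaks, valid_n = r$valid_n)
          dprobs[, cols] <- dg * aw
        }
        list(loss = total / ba$B, dprobs = dprobs)
      }
      step <- nn_train_step_cpp(model$params, model$bn_state, ba$sig, ba$feats,
                                loss_grad, model$backbone$n_blocks,
                                model$backbone$kernel_len, model$backbone$pool,
                                model$backbone$dropout)
      model$bn_state <- step$bn_state
      upd <- adam_step(model$params, step$grads, opt, cfg$lr, cfg$beta1,
                       cfg$beta2)
      model$params <- upd$params
      opt <- upd$state
      losses <- c(losses, step$loss)
      i <- j + 1L
    }
    f1 <- if (cfg$val_metric == "beat") validation_f1(model, val_records)
          else validation_f1_record(model, val_records, agg)
    history <- rbind(history, data.frame(epoch = epoch,
                                         loss = mean(losses), val_f1 = f1))
    if (verbose) {
      message(sprintf("epoch %d: loss %.4f, val mean F1 %.4f", epoch,
                      mean(losses), f1))
    }
    if (f1 > best$f1) {
      best <- list(f1 = f1, params = model$params, bn = model$bn_state,
                   epoch = epoch)
    } else if (epoch - best$epoch >= cfg$patience) {
      break
    }
  }
  model$params <- best$params
  model$bn_state <- best$bn
  list(model = model, history = history, best_epoch = best$epoch,
       best_f1 = best$f1)
}

#' Supervised pre-training on beat-annotated records
#'
#' Optimizes the categorical cross-entropy at the annotated R peaks
#' ([supervised_loss()]) for a fixed number of epochs (no early stopping).
#'
#' @param model A [wb_model()].
#' @param records Featurized, padded records with mapped beat annotations.
#' @param epochs Epoch budget; 0 returns the model unchanged.
#' @param cfg A [train_config()].
#' @return The pre-trained model.
#' @export
pretrain_supervised <- function(model, records, epochs = 10,
                                cfg = train_config()) {
  if (epochs == 0L || !length(records)) return(model)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  bs <- cfg$pretrain_batch_size %||% cfg$batch_size
  opt <- adam_init(model$params)
  for (epoch in seq_len(epochs)) {
    order_ <- sample(length(records))
    i <- 1L
    while (i <= length(order_)) {
      j <- min(i + bs - 1L, length(order_))
      batch <- records[order_[i:j]]
      ba <- batch_arrays(batch)
      loss_grad <- function(probs) {
        dprobs <- matrix(0, nrow(probs), ncol(probs))
        total <- 0
        for (b in seq_len(ba$B)) {
          cols <- ((b - 1L) * ba$L + 1L):(b * ba$L)
          pm <- probs[, cols, drop = FALSE]
          rownames(pm) <- model$classes
          r <- batch[[b]]
          use <- which(!r$beats$excluded & r$beats$pos <= ba$L)
          if (!length(use)) next
          total <- total + supervised_loss(pm, r$beats)
          ci <- match(r$beats$class[use], model$classes)
          pk <- r$beats$pos[use]
          pvals <- pm[cbind(ci, pk)]
          dprobs[cbind(ci, (b - 1L) * ba$L + pk)] <-
            -1 / pmax(pvals, 1e-12) / length(use) / ba$B
        }
        list(loss = total / ba$B, dprobs = dprobs)
      }
      step <- nn_train_step_cpp(model$params, model$bn_state, ba$sig, ba$feats,
                                loss_grad, model$backbone$n_blocks,
                                model$backbone$kernel_len, model$backbone$pool,
                                model$backbone$dropout)
      model$bn_state <- step$bn_state
      upd <- adam_step(model$params, step$grads, opt, cfg$lr, cfg$beta1,
                       cfg$beta2)
      model$params <- upd$params
      opt <- upd$state
      i <- j + 1L
    }
  }
  model
}

#' Two-stage training: supervised pre-training then weak training
#'
#' Pre-trains on a small finely annotated set ([pretrain_supervised()], fixed
#' budget `cfg$pretrain_epochs`), then continues with weakly supervised
#' training on coarsely labeled records ([train_weak()]), returning the
#' weak-stage best model. With no fine records this reduces to pure weak
#' training.
#'
#' @param model A [wb_model()].
#' @param fine_records Beat-annotated records for the supervised stage (may
#'   be empty).
#' @param coarse_records Record-label-only records for the weak stage.
#' @param val_records Validation records (beat-annotated by default).
#' @param cfg A [train_config()].
#' @param agg An [aggregation_config()].
#' @param verbose Print progress.
#' @return As [train_weak()].
#' @export
two_stage_train <- function(model, fine_records, coarse_records, val_records,
                            cfg = train_config(), agg = aggregation_config(),
                            verbose = FALSE) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  cfg_inner <- cfg
  cfg_inner$seed <- NULL  # one stream across both stages
  model <- pretrain_supervised(model, fine_records, cfg$pretrain_epochs,
                               cfg_inner)
  train_weak(model, coarse_records, val_records, cfg_inner, agg, verbose)
}
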