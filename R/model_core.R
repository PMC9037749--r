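# Model core: residual 1D-convolutional backbone configuration and parameter
# initialization, per-sample local prediction, and the aggregation mechanisms
# that map local predictions to a record-level (global) prediction.

#' Backbone configuration
#'
#' The feature extractor is a stack of residual blocks. Each block is
#' Conv - BatchNorm - ReLU - Dropout - Conv - BatchNorm, an additive merge
#' with the block input, ReLU, then max-pooling (pool size `pool`). An
#' initial convolution projects the single-lead signal to `kernels` channels
#' so the residual merge is dimension-consistent (nine convolutional layers
#' in total at the defaults). Convolution parameters use He initialization.
#'
#' @param n_blocks Number of residual blocks.
#' @param kernels Number of convolution kernels (channels) per layer.
#' @param kernel_len Kernel length in samples.
#' @param dropout Dropout rate inside each block.
#' @param pool Max-pooling factor per block; total downsampling is
#'   `pool^n_blocks`.
#' @return A list of class `backbone_config`.
#' @export
backbone_config <- function(n_blocks = 4, kernels = 32, kernel_len = 8,
                            dropout = 0.25, pool = 2) {
  stopifnot(n_blocks >= 1, kernels >= 1, kernel_len >= 1,
            dropout >= 0, dropout < 1, pool >= 2)
  structure(list(n_blocks = as.integer(n_blocks), kernels = as.integer(kernels),
                 kernel_len = as.integer(kernel_len), dropout = dropout,
                 pool = as.integer(pool)),
            class = "backbone_config")
}

#' Aggregation configuration
#'
#' @param method One of `"GAP"` (global average pooling), `"GMP"` (global max
#'   pooling), `"LSE"` (log-sum-exp pooling) or `"MGMP"` (masked global max
#'   pooling over R-peak positions).
#' @param lse_b Sharpness of the log-sum-exp approximation to the max (> 0).
#' @return A list of class `aggregation_config`.
#' @export
aggregation_config <- function(method = c("MGMP", "GMP", "GAP", "LSE"),
                               lse_b = 5) {
  method <- match.arg(method)
  stopifnot(lse_b > 0)
  structure(list(method = method, lse_b = lse_b),
            class = "aggregation_config")
}

#' Length of the backbone output for a given input length
#'
#' Each block halves the length with floor division (2500 samples map to 156
#' at the defaults).
#'
#' @param n Input length in samples.
#' @param cfg A [backbone_config()].
#' @return Integer output length.
#' @export
backbone_out_len <- function(n, cfg = backbone_config()) {
  for (i in seq_len(cfg$n_blocks)) n <- n %/% cfg$pool
  as.integer(n)
}

#' Initialize a detector model
#'
#' Creates the trainable parameters (He-initialized convolutions, unit-gamma
#' batch norms, zero-initialized head) for the backbone plus the
#' time-distributed dense prediction head over the concatenation of the
#' upsampled DNN channels and the knowledge feature channels. Consumes the
#' current R random stream, so `set.seed()` makes initialization
#' reproducible.
#'
#' @param backbone A [backbone_config()].
#' @param n_knowledge Number of knowledge feature channels.
#' @param n_classes Number of rhythm classes (N, S, V).
#' @return A list of class `wb_model` with `params`, `bn_state` and the
#'   configuration.
#' @export
wb_model <- function(backbone = backbone_config(), n_knowledge = 2,
                     n_classes = 3) {
  C <- backbone$kernels
  k <- backbone$kernel_len
  he <- function(fan_in, nrow, ncol) {
    matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
  }
  params <- list(conv0_W = he(1 * k, C, 1 * k), conv0_b = numeric(C))
  bn_state <- list()
  for (i in seq_len(backbone$n_blocks)) {
    p <- paste0("b", i, "_")
    params[[paste0(p, "W1")]] <- he(C * k, C, C * k)
    params[[paste0(p, "b1")]] <- numeric(C)
    params[[paste0(p, "g1")]] <- rep(1, C)
    params[[paste0(p, "be1")]] <- numeric(C)
    params[[paste0(p, "W2")]] <- he(C * k, C, C * k)
    params[[paste0(p, "b2")]] <- numeric(C)
    params[[paste0(p, "g2")]] <- rep(1, C)
    params[[paste0(p, "be2")]] <- numeric(C)
    bn_state[[paste0(p, "rm1")]] <- numeric(C)
    bn_state[[paste0(p, "rv1")]] <- rep(1, C)
    bn_state[[paste0(p, "rm2")]] <- numeric(C)
    bn_state[[paste0(p, "rv2")]] <- rep(1, C)
  }
  params$head_W <- he(C + n_knowledge, n_classes, C + n_knowledge)
  params$head_b <- numeric(n_classes)
  structure(list(params = params, bn_state = bn_state, backbone = backbone,
                 n_knowledge = n_knowledge, classes = AAMI_CLASSES[seq_len(n_classes)]),
            class = "wb_model")
}

#' @export
print.wb_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, 0L))
  cat(sprintf("<wb_model> %d residual blocks, %d kernels (len %d), %d parameters\n",
              x$backbone$n_blocks, x$backbone$kernels, x$backbone$kernel_len,
              n_par))
  invisible(x)
}

# Stack records into the (L x B) signal matrix and (2 x L*B) feature matrix
# the C++ kernels expect.
batch_arrays <- function(records) {
  L <- length(records[[1L]]$samples)
  B <- length(records)
  sig <- matrix(0, L, B)
  feats <- matrix(0, 2, L * B)
  for (b in seq_len(B)) {
    r <- records[[b]]
    if (length(r$samples) != L) stop("all records in a batch must share one length")
    if (is.null(r$features)) stop("records must be featurized first")
    sig[, b] <- r$samples
    feats[, ((b - 1L) * L + 1L):(b * L)] <- r$features
  }
  list(sig = sig, feats = feats, L = L, B = B)
}

#' Per-sample local prediction
#'
#' Runs the backbone on the signal, upsamples the learned feature maps back
#' to the input length (nearest-neighbor repetition), concatenates the
#' knowledge feature channels, and applies the time-distributed dense head
#' with a per-sample softmax. Inference mode: dropout off, batch norm uses
#' running statistics.
#'
#' @param model A [wb_model()].
#' @param record A featurized [ecg_record()] (see [featurize_record()]), or a
#'   list with `samples` and a 2-row `features` matrix.
#' @return A `(classes x n)` matrix of per-sample probabilities; columns sum
#'   to one.
#' @export
local_predict <- function(model, record) {
  if (length(record$samples) < model$backbone$pool^model$backbone$n_blocks) {
    stop("signal shorter than the backbone downsampling factor")
  }
  if (is.null(record$features)) stop("record must be featurized first")
  if (ncol(record$features) != length(record$samples)) {
    stop("feature maps and signal must have the same length")
  }
  out <- nn_forward_cpp(model$params, model$bn_state,
                        matrix(record$samples, ncol = 1), record$features,
                        model$backbone$n_blocks, model$backbone$kernel_len,
                        model$backbone$pool)
  probs <- out$probs
  rownames(probs) <- model$classes
  probs
}

class_row <- function(local, class) {
  if (is.matrix(local)) {
    if (is.null(class)) stop("class must be given for a prediction matrix")
    if (is.character(class)) local[class, ] else local[class, ]
  } else as.numeric(local)
}

#' Global average pooling
#'
#' Averages the local predictions of one class over all samples. Rare events
#' (a single ectopic beat in a long record) are diluted, which is why it is a
#' baseline rather than the default.
#'
#' @param local A `(classes x n)` probability matrix or a numeric vector of
#'   one class's local predictions.
#' @param class Class name or row index (when `local` is a matrix).
#' @return The pooled scalar score.
#' @export
gap <- function(local, class = NULL) {
  v <- class_row(local, class)
  if (!length(v)) stop("no local predictions to aggregate")
  mean(v)
}

#' Global max pooling
#'
#' @inheritParams gap
#' @return The maximum local prediction for the class.
#' @export
gmp <- function(local, class = NULL) {
  v <- class_row(local, class)
  if (!length(v)) stop("no local predictions to aggregate")
  max(v)
}

#' Log-sum-exp pooling
#'
#' `(1/b) log((1/n) sum_i exp(b * y_i))`: a convex approximation of the max
#' that interpolates between global average (`b -> 0`) and global max
#' (`b -> Inf`). Evaluated with a max-shift for numerical stability.
#'
#' @inheritParams gap
#' @param b Sharpness parameter, > 0.
#' @return The pooled scalar score.
#' @export
lse <- function(local, class = NULL, b = 5) {
  if (b <= 0) stop("b must be positive")
  v <- class_row(local, class)
  if (!length(v)) stop("no local predictions to aggregate")
  m <- max(v)
  m + (log(mean(exp(b * (v - m))))) / b
}

#' Masked global max pooling
#'
#' Global max pooling restricted to the local predictions at the R-peak
#' (reference) positions. Only those predictions receive gradient from the
#' record-level loss, so after training the prediction at each R peak is
#' representative of its beat.
#'
#' @inheritParams gap
#' @param rpeaks An [rpeak_set()] (or integer vector of sample indices).
#' @return The pooled scalar score.
#' @export
mgmp <- function(local, rpeaks, class = NULL) {
  idx <- if (inherits(rpeaks, "rpeak_set")) rpeaks$indices else as.integer(rpeaks)
  if (!length(idx)) stop("MGMP requires a non-empty R-peak set")
  v <- class_row(local, class)
  if (max(idx) > length(v) || min(idx) < 1L) stop("R-peak index outside signal")
  max(v[idx])
}

#' Aggregate local predictions into a global prediction
#'
#' Applies the configured mechanism independently per class. Padding samples
#' (beyond `valid_n`) are excluded from aggregation.
#'
#' @param local A `(classes x n)` probability matrix.
#' @param cfg An [aggregation_config()].
#' @param rpeaks An [rpeak_set()], required for `method = "MGMP"`.
#' @param valid_n Number of non-padding samples (default: all).
#' @return Named numeric vector of per-class scores in `[0, 1]`.
#' @export
aggregate_global <- function(local, cfg = aggregation_config(), rpeaks = NULL,
                             valid_n = NULL) {
  n <- ncol(local)
  if (is.null(valid_n)) valid_n <- n
  use <- seq_len(min(valid_n, n))
  cls <- rownames(local)
  if (is.null(cls)) cls <- as.character(seq_len(nrow(local)))
  if (cfg$method == "MGMP" && (is.null(rpeaks) ||
      !length(if (inherits(rpeaks, "rpeak_set")) rpeaks$indices else rpeaks))) {
    stop("MGMP aggregation requires R-peak positions")
  }
  out <- vapply(seq_len(nrow(local)), function(ci) {
    v <- local[ci, use]
    switch(cfg$method,
           GAP = gap(v),
           GMP = gmp(v),
           LSE = lse(v, b = cfg$lse_b),
           MGMP = mgmp(v, rpeaks))
  }, numeric(1))
  names(out) <- cls
  out
}

# Gradient of the global scores with respect to the local predictions:
# returns a (classes x n) matrix where row c holds dG_c / dlocal[c, ].
aggregate_weights <- function(local, cfg, rpeaks = NULL, valid_n = NULL) {
  n <- ncol(local)
  if (is.null(valid_n)) valid_n <- n
  use <- seq_len(min(valid_n, n))
  W <- matrix(0, nrow(local), n)
  for (ci in seq_len(nrow(local))) {
    v <- local[ci, use]
    w <- switch(cfg$method,
      GAP = rep(1 / length(v), length(v)),
      GMP = { w <- numeric(length(v)); w[which.max(v)] <- 1; w },
      LSE = { e <- exp(cfg$lse_b * (v - max(v))); e / sum(e) },
      MGMP = {
        idx <- if (inherits(rpeaks, "rpeak_set")) rpeaks$indices else as.integer(rpeaks)
        w <- numeric(length(v))
        w[idx[which.max(v[idx])]] <- 1
        w
      })
    W[ci, use] <- w
  }
  W
}
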