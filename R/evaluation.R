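# Beat-level evaluation: per-beat class decisions at R peaks, one-vs-rest
# confusion counts, AAMI-style rates (sensitivity, specificity, positive
# predictivity, accuracy, F1), precision-recall curves with step-wise
# average precision, and multi-seed stability summaries.

#' Per-beat class decisions
#'
#' The class of a beat is the argmax over the classes of the local
#' probabilities at its R-peak index; exact ties resolve to N, the a-priori
#' majority class.
#'
#' @param local A `(classes x n)` local probability matrix with row names.
#' @param rpeaks An [rpeak_set()] or integer vector of peak indices.
#' @return Character vector of per-beat classes.
#' @export
beat_decisions <- function(local, rpeaks) {
  idx <- if (inherits(rpeaks, "rpeak_set")) rpeaks$indices else as.integer(rpeaks)
  cls <- rownames(local)
  if (is.null(cls)) cls <- AAMI_CLASSES[seq_len(nrow(local))]
  n_order <- match("N", cls)
  vapply(idx, function(i) {
    p <- local[, i]
    top <- which(p == max(p))
    if (length(top) > 1L && !is.na(n_order) && n_order %in% top) top <- n_order
    cls[top[1L]]
  }, character(1))
}

#' One-vs-rest confusion counts for one class
#'
#' @param pred,truth Character vectors of per-beat classes (excluded F/Q
#'   beats already removed).
#' @param class The positive class.
#' @return Named integer vector `c(TP, FP, TN, FN)`.
#' @export
confusion_counts <- function(pred, truth, class) {
  stopifnot(length(pred) == length(truth))
  p <- pred == class
  t <- truth == class
  c(TP = sum(p & t), FP = sum(p & !t), TN = sum(!p & !t), FN = sum(!p & t))
}

#' Classification rates from confusion counts
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(FP+TN)`, positive predictivity
#' `TP/(TP+FP)`, accuracy, and F1 (harmonic mean of Sen and Ppr). Undefined
#' 0/0 ratios are reported as 0 and flagged.
#'
#' @param counts Named vector with `TP`, `FP`, `TN`, `FN`.
#' @return List with `Sen`, `Spe`, `Ppr`, `Acc`, `F1` and a `flags`
#'   character vector naming any undefined ratios.
#' @export
class_rates <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  tn <- counts[["TN"]]; fn <- counts[["FN"]]
  flags <- character()
  safe <- function(num, den, what) {
    if (den == 0) { flags <<- c(flags, what); return(0) }
    num / den
  }
  sen <- safe(tp, tp + fn, "Sen")
  spe <- safe(tn, fp + tn, "Spe")
  ppr <- safe(tp, tp + fp, "Ppr")
  acc <- safe(tp + tn, tp + fp + tn + fn, "Acc")
  f1 <- if (sen + ppr == 0) { flags <- c(flags, "F1"); 0 } else {
    2 * sen * ppr / (sen + ppr)
  }
  list(Sen = sen, Spe = spe, Ppr = ppr, Acc = acc, F1 = f1, flags = flags)
}

#' Average precision and the precision-recall curve
#'
#' Thresholds are placed at the distinct score values in descending order;
#' at threshold `n`, `Sen_n` is the recall and `Ppr_n` the precision of
#' predicting positive at score >= threshold. The step-wise area
#' `AP = sum_n (Sen_n - Sen_{n-1}) Ppr_n` is returned together with the
#' curve. Invariant to strictly monotone transforms of the scores.
#'
#' @param scores Numeric per-beat scores for the class.
#' @param truth Binary (0/1 or logical) per-beat ground truth.
#' @return List with `ap` (NA with a flag when there are no positives) and
#'   `prc`, a data.frame of `threshold`, `sen`, `ppr`.
#' @export
average_precision <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  truth <- as.integer(as.logical(truth))
  n_pos <- sum(truth)
  if (n_pos == 0L) {
    return(list(ap = NA_real_, prc = data.frame(threshold = numeric(),
                                                sen = numeric(),
                                                ppr = numeric()),
                flags = "no positives"))
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  t <- truth[ord]
  cum_tp <- cumsum(t)
  cum_pp <- seq_along(t)
  last <- which(!duplicated(s, fromLast = TRUE))  # last index of each tie group
  sen <- cum_tp[last] / n_pos
  ppr <- cum_tp[last] / cum_pp[last]
  ap <- sum(diff(c(0, sen)) * ppr)
  list(ap = ap, prc = data.frame(threshold = s[last], sen = sen, ppr = ppr),
       flags = character())
}

#' Full beat-level metrics report
#'
#' Computes per-class confusion counts, rates, precision-recall curve and
#' average precision from local predictions on a set of annotated records.
#' Excluded (F/Q) beats do not enter any count.
#'
#' @param model A [wb_model()].
#' @param records Featurized, padded records with mapped beat annotations.
#' @return A list of class `metrics_report`: per class, `counts`, the rates,
#'   `ap` and `prc`; plus `n_beats` and the decision vectors.
#' @export
evaluate_beats <- function(model, records) {
  probs <- predict_records(model, records)
  pred <- character(); truth <- character()
  score_rows <- lapply(model$classes, function(x) numeric())
  names(score_rows) <- model$classes
  for (i in seq_along(records)) {
    r <- records[[i]]
    if (is.null(r$beats) || is.null(r$beats$class)) next
    use <- !r$beats$excluded & r$beats$pos <= ncol(probs[[i]])
    if (!any(use)) next
    pk <- r$beats$pos[use]
    pred <- c(pred, beat_decisions(probs[[i]], pk))
    truth <- c(truth, r$beats$class[use])
    for (cl in model$classes) {
      score_rows[[cl]] <- c(score_rows[[cl]], probs[[i]][cl, pk])
    }
  }
  per_class <- lapply(model$classes, function(cl) {
    counts <- confusion_counts(pred, truth, cl)
    rates <- class_rates(counts)
    apc <- average_precision(score_rows[[cl]], truth == cl)
    c(list(counts = counts), rates, list(ap = apc$ap, prc = apc$prc))
  })
  names(per_class) <- model$classes
  structure(list(classes = per_class, n_beats = length(truth),
                 pred = pred, truth = truth),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %d evaluated beats\n", x$n_beats))
  for (cl in names(x$classes)) {
    m <- x$classes[[cl]]
    cat(sprintf("  %s: Sen %.3f  Spe %.3f  Ppr %.3f  Acc %.3f  F1 %.3f  AP %s\n",
                cl, m$Sen, m$Spe, m$Ppr, m$Acc, m$F1,
                ifelse(is.na(m$ap), "NA", sprintf("%.3f", m$ap))))
  }
  invisible(x)
}

#' Write a metrics report to JSON and CSV
#'
#' @param report A `metrics_report` from [evaluate_beats()].
#' @param dir Output directory (created if needed). Writes `metrics.json`,
#'   `metrics.csv` and one `prc_<class>.csv` per class.
#' @return `dir`, invisibly.
#' @export
write_metrics_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- do.call(rbind, lapply(names(report$classes), function(cl) {
    m <- report$classes[[cl]]
    data.frame(class = cl, TP = m$counts[["TP"]], FP = m$counts[["FP"]],
               TN = m$counts[["TN"]], FN = m$counts[["FN"]], Sen = m$Sen,
               Spe = m$Spe, Ppr = m$Ppr, Acc = m$Acc, F1 = m$F1, AP = m$ap)
  }))
  write.table(tab, file.path(dir, "metrics.csv"), sep = ",",
              row.names = FALSE, qmethod = "double")
  jsonlite::write_json(tab, file.path(dir, "metrics.json"), auto_unbox = TRUE,
                       digits = NA)
  for (cl in names(report$classes)) {
    write.table(report$classes[[cl]]$prc,
                file.path(dir, paste0("prc_", cl, ".csv")), sep = ",",
                row.names = FALSE)
  }
  invisible(dir)
}

#' Multi-seed stability summary
#'
#' @param f1_per_seed Numeric vector of F1 scores from independent training
#'   runs (or a matrix, one column per class).
#' @return List with `mean` and `sd` (sample standard deviation; NA with a
#'   flag for a single run).
#' @export
stability_summary <- function(f1_per_seed) {
  if (is.matrix(f1_per_seed)) {
    return(list(mean = colMeans(f1_per_seed),
                sd = apply(f1_per_seed, 2, stats::sd),
                flags = if (nrow(f1_per_seed) < 2L) "single run" else character()))
  }
  list(mean = mean(f1_per_seed), sd = stats::sd(f1_per_seed),
       flags = if (length(f1_per_seed) < 2L) "single run" else character())
}

#' Match detected R peaks to reference beat annotations
#'
#' Nearest-peak matching within a 150 ms tolerance, used only when beats are
#' located by the detector instead of reference annotations.
#'
#' @param detected Integer vector of detected peak indices.
#' @param reference Integer vector of annotated peak indices.
#' @param rate Sampling rate, Hz.
#' @param tol_s Matching tolerance, seconds.
#' @return Integer vector: for each reference beat, the index into `detected`
#'   (NA when unmatched).
#' @export
match_beats <- function(detected, reference, rate, tol_s = 0.15) {
  tol <- tol_s * rate
  vapply(reference, function(p) {
    if (!length(detected)) return(NA_integer_)
    d <- abs(detected - p)
    j <- which.min(d)
    if (d[j] <= tol) j else NA_integer_
  }, integer(1))
}
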