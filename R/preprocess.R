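# Preprocessing: baseline-wander removal, band-pass filtering, rate and
# amplitude unification, record-label complementation, fixed-length padding.
# Pipeline order: baseline -> bandpass -> resample -> normalize.

#' Preprocessing configuration
#'
#' @param baseline_window Moving-average window for baseline estimation, s.
#' @param band_low,band_high Band-pass corner frequencies, Hz.
#' @param target_rate Unified sampling rate, Hz.
#' @param resample_tolerance Records within this many Hz of `target_rate`
#'   are left at their native rate.
#' @param pad_length Fixed record length for batch processing, s.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(baseline_window = 1.0, band_low = 0.1,
                              band_high = 30, target_rate = 125,
                              resample_tolerance = 3, pad_length = 20) {
  stopifnot(band_low > 0, band_low < band_high, band_high < target_rate / 2,
            baseline_window > 0, pad_length > 0)
  structure(list(baseline_window = baseline_window, band_low = band_low,
                 band_high = band_high, target_rate = target_rate,
                 resample_tolerance = resample_tolerance,
                 pad_length = pad_length),
            class = "preprocess_config")
}

#' Remove baseline wander by moving-average subtraction
#'
#' Estimates the baseline as a centered moving average (window shrinks at the
#' record edges, so the estimate has no phase shift) and subtracts it.
#'
#' @param samples Amplitude vector.
#' @param rate Sampling rate, Hz.
#' @param window Window size, seconds.
#' @return Baseline-corrected amplitude vector of the same length.
#' @export
remove_baseline <- function(samples, rate, window = 1.0) {
  n <- length(samples)
  if (n == 0L) stop("empty signal")
  w <- max(1L, round(window * rate))
  half_lo <- (w - 1L) %/% 2L
  half_hi <- w - 1L - half_lo
  cs <- cumsum(c(0, samples))
  i <- seq_len(n)
  lo <- pmax(i - half_lo, 1L)
  hi <- pmin(i + half_hi, n)
  baseline <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  samples - baseline
}

#' Zero-phase band-pass filter
#'
#' 2nd-order Butterworth band-pass applied forward and backward
#' (`signal::filtfilt`), so QRS peaks are not shifted in time.
#'
#' @param samples Amplitude vector.
#' @param rate Sampling rate, Hz (must exceed twice `high`).
#' @param low,high Pass band corners, Hz.
#' @return Filtered amplitude vector of the same length.
#' @export
bandpass <- function(samples, rate, low = 0.1, high = 30) {
  if (rate <= 2 * high) stop("sampling rate must exceed twice the upper corner")
  bf <- signal::butter(2, c(low, high) / (rate / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, samples))
}

#' Resample a signal to a target rate
#'
#' Rates within `tolerance` of the target are passed through unchanged (for
#' example 128 Hz recordings when targeting 125 Hz); otherwise the signal is
#' resampled in the frequency domain to length `round(n * target / rate)`.
#' Fourier resampling introduces no phase shift, so R-peak positions scale
#' exactly with the rate; in the preprocessing pipeline the signal is already
#' band-limited (0.1-30 Hz) before downsampling, so no aliasing occurs.
#'
#' @param samples Amplitude vector.
#' @param rate Native sampling rate, Hz.
#' @param target Target rate, Hz.
#' @param tolerance Pass-through tolerance, Hz.
#' @return List with `samples` and the effective `rate`.
#' @export
resample_to <- function(samples, rate, target = 125, tolerance = 3) {
  stopifnot(rate > 0, target > 0)
  if (abs(rate - target) <= tolerance) {
    return(list(samples = samples, rate = rate))
  }
  n <- length(samples)
  n_out <- round(n * target / rate)
  X <- stats::fft(samples)
  Y <- complex(length.out = n_out)
  m <- min(n, n_out)
  nyq <- m %/% 2L + 1L
  Y[seq_len(nyq)] <- X[seq_len(nyq)]
  n_neg <- m - nyq
  if (n_neg > 0L) {
    Y[(n_out - n_neg + 1L):n_out] <- X[(n - n_neg + 1L):n]
  }
  out <- Re(stats::fft(Y, inverse = TRUE)) / n
  list(samples = out, rate = target)
}

#' Normalize a signal to zero mean and unit variance
#'
#' @param samples Amplitude vector.
#' @return Standardized vector; a constant input yields zeros with a warning.
#' @export
normalize_signal <- function(samples) {
  mu <- mean(samples)
  s <- sqrt(mean((samples - mu)^2))  # population variance: [1, 3] -> [-1, 1]
  if (!is.finite(s) || s == 0) {
    warning("constant signal cannot be normalized; returning zeros")
    return(rep(0, length(samples)))
  }
  (samples - mu) / s
}

#' Complement a record-level label set
#'
#' Coarse annotations of a recording that contains both sinus and ectopic
#' episodes usually omit the sinus label. If the label set contains S or V
#' and contains neither supraventricular tachyarrhythmia (`SVTA`) nor
#' idioventricular rhythm (`IVR`), sinus beats are almost certainly present
#' too, so N is added. Idempotent.
#'
#' @param label_set Character vector over `c("N","S","V","SVTA","IVR")`.
#' @return Possibly augmented label set.
#' @export
complement_labels <- function(label_set) {
  if (any(c("S", "V") %in% label_set) &&
      !any(AUX_TAGS %in% label_set) &&
      !("N" %in% label_set)) {
    label_set <- c(label_set, "N")
  }
  label_set
}

#' Pad or truncate a record to a fixed duration
#'
#' Zero-pads (or truncates) at the end to exactly `round(pad_length * rate)`
#' samples; beat annotations beyond the cut are dropped. The original sample
#' count is kept in the `valid_n` field so that padding can be excluded from
#' aggregation.
#'
#' @param record An [ecg_record()].
#' @param pad_length Target duration, seconds.
#' @return The padded/truncated record, with `valid_n` attached.
#' @export
pad_or_truncate <- function(record, pad_length = 20) {
  n_target <- round(pad_length * record$sampling_rate)
  n <- length(record$samples)
  if (n >= n_target) {
    record$samples <- record$samples[seq_len(n_target)]
    if (!is.null(record$beats)) {
      record$beats <- as_beat_annotation(
        record$beats[record$beats$pos <= n_target, , drop = FALSE])
    }
    if (!is.null(record$features)) {
      record$features <- record$features[, seq_len(n_target), drop = FALSE]
    }
    record$valid_n <- n_target
  } else {
    record$samples <- c(record$samples, rep(0, n_target - n))
    if (!is.null(record$features)) {
      record$features <- cbind(record$features,
                               matrix(0, nrow(record$features), n_target - n))
    }
    record$valid_n <- n
  }
  if (!is.null(record$rpeaks)) {
    keep <- record$rpeaks$indices <= n_target
    record$rpeaks <- rpeak_set(record$rpeaks$indices[keep],
                               record$sampling_rate)
  }
  record
}

#' Preprocess an ECG record
#'
#' Applies the full pipeline in fixed order — baseline removal, zero-phase
#' band-pass, resampling to the target rate, amplitude standardization — and
#' complements the record-level label set. Beat positions are rescaled with
#' the resampling ratio.
#'
#' @param record An [ecg_record()].
#' @param cfg A [preprocess_config()].
#' @return The preprocessed record (`preprocessed = TRUE` attached).
#' @export
preprocess_record <- function(record, cfg = preprocess_config()) {
  x <- remove_baseline(record$samples, record$sampling_rate, cfg$baseline_window)
  x <- bandpass(x, record$sampling_rate, cfg$band_low, cfg$band_high)
  rs <- resample_to(x, record$sampling_rate, cfg$target_rate,
                    cfg$resample_tolerance)
  if (rs$rate != record$sampling_rate && !is.null(record$beats)) {
    ratio <- rs$rate / record$sampling_rate
    pos <- pmax(1L, pmin(length(rs$samples), as.integer(round((record$beats$pos - 1L) * ratio)) + 1L))
    beats <- record$beats
    beats$pos <- pos
    record$beats <- as_beat_annotation(beats)
  }
  record$samples <- normalize_signal(rs$samples)
  record$sampling_rate <- rs$rate
  record$label_set <- complement_labels(record$label_set)
  record$preprocessed <- TRUE
  record
}
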