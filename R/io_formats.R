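#' @useDynLib weakbeat, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif median sd quantile
#' @importFrom utils read.table write.table head tail
"_PACKAGE"

# AAMI beat classes handled by the detector. F and Q beats are carried through
# the pipeline but flagged excluded: they are skipped in losses and metrics only.
AAMI_CLASSES <- c("N", "S", "V")
EXCLUDED_CLASS <- "X"

# Auxiliary record-level rhythm tags that participate in label complementation.
AUX_TAGS <- c("SVTA", "IVR")

# PhysioBank beat symbol -> AAMI class (N / S / V), everything else excluded.
PHYSIOBANK_MAP <- c(
  "N" = "N", "L" = "N", "R" = "N", "e" = "N", "j" = "N",
  "A" = "S", "a" = "S", "J" = "S", "S" = "S",
  "V" = "V", "E" = "V",
  "F" = "X", "Q" = "X", "f" = "X", "/" = "X", "X" = "X"
)

#' Construct an ECG record
#'
#' Container for one lead of an ECG recording: the sample sequence, its
#' sampling rate, an optional record-level label set over the AAMI classes
#' (plus auxiliary rhythm tags), and optional beat annotations.
#'
#' @param record_id Character identifier.
#' @param samples Numeric vector of amplitudes (mV).
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param lead Lead name (e.g. `"II"`, `"MLII"`).
#' @param label_set Character vector over `c("N","S","V","SVTA","IVR")`.
#' @param beats Optional beat annotation, see [beat_annotation()].
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(record_id, samples, sampling_rate, lead = "II",
                       label_set = character(), beats = NULL) {
  if (length(samples) == 0L) stop("samples must be non-empty")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be > 0")
  }
  vocab <- c(AAMI_CLASSES, AUX_TAGS)
  label_set <- unique(as.character(label_set))
  if (length(label_set) && !all(label_set %in% vocab)) {
    stop("label_set outside vocabulary: ",
         paste(setdiff(label_set, vocab), collapse = ", "))
  }
  if (!is.null(beats)) {
    beats <- as_beat_annotation(beats)
    if (nrow(beats) && (min(beats$pos) < 1L || max(beats$pos) > length(samples))) {
      stop("beat positions outside the signal")
    }
  }
  structure(
    list(record_id = as.character(record_id),
         samples = as.numeric(samples),
         sampling_rate = as.numeric(sampling_rate),
         lead = as.character(lead),
         label_set = label_set,
         beats = beats),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record %s> lead %s, %d samples @ %g Hz (%.1f s)\n",
              x$record_id, x$lead, length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate))
  cat("  labels: {", paste(sort(x$label_set), collapse = ", "), "}\n")
  if (!is.null(x$beats)) cat("  beats:", nrow(x$beats), "annotated\n")
  invisible(x)
}

#' Construct a beat annotation table
#'
#' @param positions Strictly increasing 1-based sample indices of R peaks.
#' @param symbols Per-beat symbols (PhysioBank vocabulary or AAMI classes).
#' @return A `data.frame` with columns `pos` and `symbol` (and, after
#'   [map_beat_symbols()], `class` and `excluded`).
#' @export
beat_annotation <- function(positions, symbols) {
  positions <- as.integer(positions)
  symbols <- as.character(symbols)
  if (length(positions) != length(symbols)) {
    stop("positions and symbols must have equal length")
  }
  if (length(positions) > 1L && any(diff(positions) <= 0L)) {
    stop("positions must be strictly increasing")
  }
  structure(data.frame(pos = positions, symbol = symbols,
                       stringsAsFactors = FALSE),
            class = c("beat_annotation", "data.frame"))
}

as_beat_annotation <- function(x) {
  if (inherits(x, "beat_annotation")) return(x)
  stopifnot(is.data.frame(x), all(c("pos", "symbol") %in% names(x)))
  out <- beat_annotation(x$pos, x$symbol)
  for (extra in intersect(c("class", "excluded"), names(x))) out[[extra]] <- x[[extra]]
  out
}

#' Map beat symbols to AAMI classes
#'
#' Translates PhysioBank beat symbols to the AAMI classes N (normal or bundle
#' branch block), S (supraventricular ectopic) and V (ventricular ectopic).
#' Fusion (F) and unknown/paced (Q-type) beats are retained but flagged
#' `excluded`: they still anchor R-peak-based features, and are skipped only
#' in losses and metrics. Unrecognized symbols trigger a warning and are
#' excluded. The operation is idempotent on already-mapped annotations.
#'
#' @param beats A [beat_annotation()].
#' @param mapping Either `"physiobank"` or a named character vector
#'   symbol -> class.
#' @return The annotation with `class` and `excluded` columns filled.
#' @export
map_beat_symbols <- function(beats, mapping = "physiobank") {
  beats <- as_beat_annotation(beats)
  map <- if (is.character(mapping) && length(mapping) == 1L) {
    switch(mapping, physiobank = PHYSIOBANK_MAP,
           stop("unknown mapping: ", mapping))
  } else mapping
  cls <- unname(map[beats$symbol])
  unknown <- is.na(cls)
  if (any(unknown)) {
    warning("unknown beat symbols excluded: ",
            paste(unique(beats$symbol[unknown]), collapse = ", "))
    cls[unknown] <- EXCLUDED_CLASS
  }
  beats$class <- cls
  beats$symbol <- cls          # idempotent: classes map to themselves
  beats$excluded <- cls == EXCLUDED_CLASS
  beats
}

#' Derive the record-level label set from beat annotations
#'
#' The label set is the set of AAMI classes present among non-excluded beats.
#' Used to build coarse (record-level) labels from finely annotated or
#' synthetic data.
#'
#' @param beats A mapped [beat_annotation()] (see [map_beat_symbols()]).
#' @return Character vector of classes, a subset of `c("N","S","V")`.
#' @export
derive_record_labels <- function(beats) {
  if (is.null(beats) || nrow(beats) == 0L) return(character())
  if (is.null(beats$class)) stop("beats must be mapped to AAMI classes first")
  sort(unique(beats$class[!beats$excluded]))
}

#' Read the bundled SNOMED CT -> AAMI mapping table
#'
#' Record-level SNOMED CT codes used by coarsely annotated challenge datasets,
#' mapped to AAMI classes; codes not listed map to N.
#'
#' @return A data.frame with columns `code`, `class`, `description`.
#' @export
snomed_mapping <- function() {
  read.table(system.file("extdata", "snomed_aami_map.csv", package = "weakbeat"),
             header = TRUE, sep = ",", colClasses = "character")
}

# ---------------------------------------------------------------------------
# Columnar text format: header line "record_id<TAB>rate<TAB>lead<TAB>lab1,lab2"
# followed by one sample value per line; beat annotations in a "<path>.beats"
# sidecar of "index<TAB>symbol" lines (1-based indices).

#' Write an ECG record in the columnar text format
#'
#' @param record An [ecg_record()].
#' @param path Output file path; beats (if any) go to `<path>.beats`.
#' @return `path`, invisibly.
#' @export
write_record_columnar <- function(record, path) {
  header <- paste(record$record_id, format(record$sampling_rate, digits = 12),
                  record$lead, paste(record$label_set, collapse = ","),
                  sep = "\t")
  writeLines(c(header, format(record$samples, digits = 12, trim = TRUE,
                              scientific = FALSE)), path)
  if (!is.null(record$beats) && nrow(record$beats)) {
    writeLines(paste(record$beats$pos, record$beats$symbol, sep = "\t"),
               paste0(path, ".beats"))
  }
  invisible(path)
}

read_record_columnar <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty record file: ", path)
  hdr <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(hdr) < 3L) stop("malformed columnar header in ", path)
  labels <- if (length(hdr) >= 4L && nzchar(hdr[[4L]])) {
    strsplit(hdr[[4L]], ",", fixed = TRUE)[[1L]]
  } else character()
  beats <- NULL
  sidecar <- paste0(path, ".beats")
  if (file.exists(sidecar)) {
    tab <- read.table(sidecar, sep = "\t", col.names = c("pos", "symbol"),
                      colClasses = c("integer", "character"))
    beats <- beat_annotation(tab$pos, tab$symbol)
  }
  ecg_record(hdr[[1L]], as.numeric(lines[-1L]), as.numeric(hdr[[2L]]),
             lead = hdr[[3L]], label_set = labels, beats = beats)
}

#' Read an ECG record (WFDB-style or columnar)
#'
#' Dispatches on the file extension: `.hea` headers are read as WFDB records
#' (signal formats 212 and 16), anything else as the columnar text format.
#' When several leads are present, lead II is preferred, then MLII, then the
#' first lead.
#'
#' @param path Path to a `.hea` header or a columnar record file.
#' @param lead_preference Lead names in order of preference.
#' @return An [ecg_record()] for the selected lead.
#' @export
read_record <- function(path, lead_preference = c("II", "MLII")) {
  if (!file.exists(path)) stop("no such record file: ", path)
  if (grepl("\\.hea$", path)) {
    read_record_wfdb(path, lead_preference)
  } else {
    read_record_columnar(path)
  }
}

# ---------------------------------------------------------------------------
# Minimal WFDB reader: text .hea header, .dat signal in format 212 (two
# 12-bit samples per 3 bytes) or 16 (little-endian int16), MIT .atr beat
# annotations. Amplitudes are converted to physical units via gain/baseline.

read_record_wfdb <- function(hea_path, lead_preference = c("II", "MLII")) {
  lines <- readLines(hea_path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) stop("empty WFDB header: ", hea_path)
  rec <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  name <- sub("/.*$", "", rec[[1L]])
  nsig <- as.integer(rec[[2L]])
  fs <- if (length(rec) >= 3L) as.numeric(sub("/.*$", "", rec[[3L]])) else 250
  nsamp <- if (length(rec) >= 4L) as.numeric(rec[[4L]]) else NA_real_
  if (is.na(nsig) || nsig < 1L) stop("WFDB header declares no signals")
  if (length(lines) < 1L + nsig) stop("WFDB header truncated")

  sig <- lapply(lines[1L + seq_len(nsig)], function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1L]]
    fmt <- as.integer(sub("x.*|:.*|\\+.*", "", f[[2L]]))
    gain_field <- if (length(f) >= 3L) f[[3L]] else "200"
    gain <- as.numeric(sub("\\(.*", "", sub("/.*", "", gain_field)))
    baseline <- if (grepl("\\(", gain_field)) {
      as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_field))
    } else if (length(f) >= 5L) as.numeric(f[[5L]]) else 0
    if (is.na(gain) || gain == 0) gain <- 200
    desc <- if (length(f) >= 9L) paste(f[9:length(f)], collapse = " ") else ""
    list(file = f[[1L]], format = fmt, gain = gain, baseline = baseline,
         lead = desc)
  })

  dat_path <- file.path(dirname(hea_path), sig[[1L]]$file)
  if (!file.exists(dat_path)) stop("missing WFDB signal file: ", dat_path)
  raw <- readBin(dat_path, "raw", n = file.size(dat_path))
  fmt <- sig[[1L]]$format
  adc <- if (fmt == 212L) {
    decode_fmt212(raw)
  } else if (fmt == 16L) {
    readBin(raw, "integer", n = length(raw) %/% 2L, size = 2L,
            signed = TRUE, endian = "little")
  } else stop("unsupported WFDB signal format: ", fmt)
  mat <- matrix(adc[seq_len((length(adc) %/% nsig) * nsig)], nrow = nsig)
  if (!is.na(nsamp) && nsamp > 0 && ncol(mat) > nsamp) mat <- mat[, seq_len(nsamp), drop = FALSE]

  leads <- vapply(sig, `[[`, "", "lead")
  pick <- 1L
  for (want in lead_preference) {
    hit <- which(toupper(leads) == toupper(want))
    if (length(hit)) { pick <- hit[[1L]]; break }
  }
  samples <- (mat[pick, ] - sig[[pick]]$baseline) / sig[[pick]]$gain

  beats <- NULL
  atr_path <- file.path(dirname(hea_path), paste0(name, ".atr"))
  if (file.exists(atr_path)) beats <- read_annotations_atr(atr_path)
  if (!is.null(beats) && nrow(beats)) {
    beats <- beats[beats$pos >= 1L & beats$pos <= length(samples), , drop = FALSE]
    beats <- as_beat_annotation(beats)
  }
  ecg_record(name, samples, fs, lead = leads[pick], beats = beats)
}

decode_fmt212 <- function(raw) {
  n3 <- (length(raw) %/% 3L) * 3L
  b <- as.integer(raw[seq_len(n3)])
  b0 <- b[seq(1L, n3, by = 3L)]
  b1 <- b[seq(2L, n3, by = 3L)]
  b2 <- b[seq(3L, n3, by = 3L)]
  s1 <- b0 + bitwShiftL(bitwAnd(b1, 0x0FL), 8L)
  s2 <- b2 + bitwShiftL(bitwAnd(bitwShiftR(b1, 4L), 0x0FL), 8L)
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  as.integer(rbind(s1, s2))
}

# MIT annotation codes -> PhysioBank symbols (beat types plus a few event
# types; events are filtered out of the beat table).
ATR_CODE_SYMBOLS <- c(
  "1" = "N", "2" = "L", "3" = "R", "4" = "a", "5" = "V", "6" = "F",
  "7" = "J", "8" = "A", "9" = "S", "10" = "E", "11" = "j", "12" = "/",
  "13" = "Q", "34" = "e", "38" = "f", "41" = "r"
)

read_annotations_atr <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  n <- (length(raw) %/% 2L) * 2L
  pos <- 0L
  t_cur <- 0
  out_pos <- integer()
  out_sym <- character()
  i <- 1L
  while (i + 1L <= n) {
    lo <- as.integer(raw[i]); hi <- as.integer(raw[i + 1L])
    i <- i + 2L
    code <- bitwShiftR(hi, 2L)
    interval <- bitwOr(bitwShiftL(bitwAnd(hi, 0x03L), 8L), lo)
    if (code == 0L && interval == 0L) break            # end of annotations
    if (code == 59L) {                                  # SKIP: 4-byte interval
      if (i + 3L > n) break
      high <- as.integer(raw[i]) + bitwShiftL(as.integer(raw[i + 1L]), 8L)
      low <- as.integer(raw[i + 2L]) + bitwShiftL(as.integer(raw[i + 3L]), 8L)
      t_cur <- t_cur + low + high * 65536
      i <- i + 4L
    } else if (code == 63L) {                           # AUX: skip payload
      i <- i + interval + (interval %% 2L)
    } else if (code %in% c(60L, 61L, 62L)) {            # NUM/SUB/CHN: no time
    } else {
      t_cur <- t_cur + interval
      sym <- ATR_CODE_SYMBOLS[as.character(code)]
      if (!is.na(sym)) {
        out_pos <- c(out_pos, as.integer(t_cur) + 1L)   # 1-based sample index
        out_sym <- c(out_sym, unname(sym))
      }
    }
  }
  beat_annotation(out_pos, out_sym)
}
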