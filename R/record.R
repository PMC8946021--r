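#' ECG record container
#'
#' Holds a single-lead sampled signal with its sampling rate, amplitude
#' resolution and optional beat annotations. Annotation indices are 0-based
#' sample numbers everywhere in this package (WFDB annotation indices pass
#' through unchanged).
#'
#' @param samples numeric vector of amplitudes (mV unless `units` says
#'   otherwise).
#' @param fs sampling frequency, Hz (> 0).
#' @param bits_per_sample ADC resolution used for compression-ratio
#'   bookkeeping; 11 matches ambulatory arrhythmia recorders.
#' @param record_id identifier string.
#' @param annotations `NULL`, or a data.frame with columns `r_index`
#'   (0-based, strictly increasing, within the signal) and `class_label`.
#' @param units amplitude units flag, `"mV"` or `"adu"`.
#' @return an object of class `ecg_record`.
#' @export
ecg_record <- function(samples, fs, bits_per_sample = 11L, record_id = "record",
                       annotations = NULL, units = "mV") {
  if (fs <= 0) stop_cs("fs must be positive, got %g", fs, class = "cardiocs_bad_input")
  samples <- as.numeric(samples)
  if (!is.null(annotations)) {
    stopifnot(is.data.frame(annotations),
              all(c("r_index", "class_label") %in% names(annotations)))
    r <- annotations$r_index
    if (length(r) && (any(diff(r) <= 0) || any(r < 0) || any(r >= length(samples))))
      stop_cs("annotation indices must be strictly increasing and inside [0, %d)",
              length(samples), class = "cardiocs_bad_input")
  }
  structure(list(samples = samples, fs = fs,
                 bits_per_sample = as.integer(bits_per_sample),
                 record_id = record_id, annotations = annotations,
                 units = units),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record '%s'> %d samples @ %g Hz (%.1f s), %d bits, %s\n",
              x$record_id, length(x$samples), x$fs, length(x$samples) / x$fs,
              x$bits_per_sample, x$units))
  if (!is.null(x$annotations))
    cat(sprintf("  %d annotated beats, classes: %s\n", nrow(x$annotations),
                paste(sort(unique(x$annotations$class_label)), collapse = " ")))
  invisible(x)
}

#' @export
plot.ecg_record <- function(x, from = 0, to = min(10, length(x$samples) / x$fs), ...) {
  i <- which((seq_along(x$samples) - 1) / x$fs >= from &
             (seq_along(x$samples) - 1) / x$fs <= to)
  graphics::plot((i - 1) / x$fs, x$samples[i], type = "l",
                 xlab = "time (s)", ylab = sprintf("amplitude (%s)", x$units),
                 main = x$record_id, ...)
  if (!is.null(x$annotations)) {
    r <- x$annotations$r_index
    r <- r[r >= min(i) - 1 & r <= max(i) - 1]
    graphics::points(r / x$fs, x$samples[r + 1], col = 2, pch = 4)
  }
  invisible(x)
}

#' Write an ECG record as CSV plus a JSON sidecar
#'
#' The CSV has two columns, `sample_index` (0-based) and `amplitude`; the
#' sidecar (same path with extension `.json`) stores `fs`, `bits_per_sample`,
#' `record_id`, `units` and, when present, 0-based `r_indices` and
#' `class_labels`.
#'
#' @param record an [ecg_record()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_csv_record <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  df <- data.frame(sample_index = seq_along(record$samples) - 1L,
                   amplitude = record$samples)
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(fs = record$fs, bits_per_sample = record$bits_per_sample,
               record_id = record$record_id, units = record$units)
  if (!is.null(record$annotations)) {
    side$r_indices <- record$annotations$r_index
    side$class_labels <- record$annotations$class_label
  }
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.[^.]*$", ".json", path)

#' Read an ECG record from CSV (with optional JSON sidecar)
#'
#' @param path CSV with columns `sample_index`, `amplitude` (or a single
#'   amplitude column).
#' @param fs sampling frequency; required when no sidecar supplies it.
#' @param sidecar path to the JSON sidecar; defaults to `path` with a `.json`
#'   extension when that file exists.
#' @return an [ecg_record()]; annotations are empty when no sidecar is given.
#' @export
read_csv_record <- function(path, fs = NULL, sidecar = NULL) {
  if (!file.exists(path)) stop_cs("no such file: %s", path, class = "cardiocs_io")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  col <- if ("amplitude" %in% names(df)) df$amplitude else df[[ncol(df)]]
  num <- suppressWarnings(as.numeric(col))
  if (anyNA(num)) {
    bad <- which(is.na(num))[1]
    stop_cs("non-numeric amplitude at data row %d of %s", bad, path,
            class = "cardiocs_io")
  }
  if (is.null(sidecar)) {
    cand <- sidecar_path(path)
    if (file.exists(cand)) sidecar <- cand
  }
  meta <- if (!is.null(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE) else list()
  fs <- fs %||% meta$fs
  if (is.null(fs) || fs <= 0)
    stop_cs("fs must be supplied (argument or sidecar) and positive",
            class = "cardiocs_bad_input")
  ann <- NULL
  if (!is.null(meta$r_indices) && length(meta$r_indices))
    ann <- data.frame(r_index = as.integer(meta$r_indices),
                      class_label = meta$class_labels %||% rep(NA_integer_, length(meta$r_indices)))
  ecg_record(num, fs = fs,
             bits_per_sample = meta$bits_per_sample %||% 11L,
             record_id = meta$record_id %||% sub("\\.[^.]*$", "", basename(path)),
             annotations = ann, units = meta$units %||% "mV")
}
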