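# Distortion and compression scoring: PRD, PRDN, CR (bit ratio) and
# QS = CR / PRD.

#' Percentage root-mean-square difference
#'
#' `PRD = 100 * sqrt(sum((x - xhat)^2) / sum(x^2))`.
#'
#' @param x original signal (nonzero energy).
#' @param xhat reconstruction, same length.
#' @return PRD in percent.
#' @export
prd <- function(x, xhat) {
  if (length(x) != length(xhat))
    stop_cs("length mismatch: %d vs %d", length(x), length(xhat),
            class = "cardiocs_bad_input")
  e2 <- sum(x^2)
  if (e2 <= .EPS)
    stop_cs("PRD undefined for a zero-energy original", class = "cardiocs_bad_input")
  100 * sqrt(sum((x - xhat)^2) / e2)
}

#' Normalized percentage root-mean-square difference
#'
#' `PRDN = 100 * sqrt(sum((x - xhat)^2) / sum((x - mean(x))^2))`: the
#' error energy is referred to the mean-removed original, so a DC offset in
#' the original does not flatter the score. `PRDN >= PRD`, with equality iff
#' the original has zero mean.
#'
#' @inheritParams prd
#' @return PRDN in percent.
#' @export
prdn <- function(x, xhat) {
  if (length(x) != length(xhat))
    stop_cs("length mismatch: %d vs %d", length(x), length(xhat),
            class = "cardiocs_bad_input")
  v <- sum((x - mean(x))^2)
  if (v <= .EPS)
    stop_cs("PRDN undefined for a constant original", class = "cardiocs_bad_input")
  100 * sqrt(sum((x - xhat)^2) / v)
}

#' Compression ratio from bit counts
#'
#' `CR = (n_samples * bits_orig) / (m_measurements * bits_comp)`: the ratio
#' of bits in the original representation to bits in the compressed one.
#' With equal bit depths this reduces to `n_samples / m_measurements`, e.g.
#' 300/20 = 15 and 300/75 = 4; for 301-sample patterns the 15:1 label
#' realizes 301/20 = 15.05.
#'
#' @param n_samples original window length.
#' @param m_measurements number of retained measurements.
#' @param bits_orig,bits_comp bit depths (default 11 each).
#' @return the ratio (dimensionless).
#' @export
compression_ratio <- function(n_samples, m_measurements, bits_orig = 11L,
                              bits_comp = 11L) {
  if (n_samples <= 0 || m_measurements <= 0 || bits_orig <= 0 || bits_comp <= 0)
    stop_cs("all bit-count arguments must be positive", class = "cardiocs_bad_input")
  (n_samples * bits_orig) / (m_measurements * bits_comp)
}

#' Quality score
#'
#' `QS = CR / PRD`: compression achieved per percent of distortion; higher
#' is better.
#'
#' @param cr compression ratio.
#' @param prd PRD in percent (> 0).
#' @return QS (dimensionless).
#' @export
quality_score <- function(cr, prd) {
  if (any(prd <= 0)) stop_cs("QS undefined for PRD <= 0", class = "cardiocs_bad_input")
  cr / prd
}

#' Per-window distortion report
#'
#' @param frame_id identifiers.
#' @param prd,prdn per-window percentages.
#' @param cr compression ratio (scalar).
#' @param record_id source record.
#' @return data.frame of class `distortion_report` with one row per window
#'   and attributes `cr` and `record_id`; `summary()`/[aggregate_reports()]
#'   reduce it.
#' @export
distortion_report <- function(frame_id, prd, prdn, cr, record_id = "record") {
  df <- data.frame(record_id = record_id, frame_id = frame_id,
                   prd = prd, prdn = prdn)
  attr(df, "cr") <- cr
  class(df) <- c("distortion_report", "data.frame")
  df
}

#' Aggregate distortion reports across records
#'
#' Each report is first reduced to its per-record mean PRD/PRDN, and the
#' returned averages are unweighted means of those per-record means (so a
#' long record does not dominate a short one). Per-record rows are retained.
#'
#' @param reports a list of `distortion_report` objects (or a single one).
#' @return data.frame of class `distortion_summary` with one row per record
#'   plus attributes `avg_prd`, `avg_prdn`, `avg_prd_framewise`,
#'   `avg_prdn_framewise`, `cr`, `qs`.
#' @export
aggregate_reports <- function(reports) {
  if (inherits(reports, "distortion_report")) reports <- list(reports)
  if (!length(reports)) stop_cs("no reports to aggregate", class = "cardiocs_bad_input")
  per <- do.call(rbind, lapply(reports, function(r) {
    data.frame(record_id = r$record_id[1], n_frames = nrow(r),
               prd = mean(r$prd), prdn = mean(r$prdn))
  }))
  all_rows <- do.call(rbind, lapply(reports, as.data.frame))
  cr <- attr(reports[[1]], "cr")
  out <- per
  attr(out, "avg_prd") <- mean(per$prd)
  attr(out, "avg_prdn") <- mean(per$prdn)
  attr(out, "avg_prd_framewise") <- mean(all_rows$prd)
  attr(out, "avg_prdn_framewise") <- mean(all_rows$prdn)
  attr(out, "cr") <- cr
  attr(out, "qs") <- if (!is.null(cr)) quality_score(cr, mean(per$prd)) else NULL
  class(out) <- c("distortion_summary", "data.frame")
  out
}

#' @export
print.distortion_summary <- function(x, ...) {
  cat(sprintf("Distortion over %d record(s): AVG PRD %.3f%%, AVG PRDN %.3f%%",
              nrow(x), attr(x, "avg_prd"), attr(x, "avg_prdn")))
  if (!is.null(attr(x, "cr")))
    cat(sprintf(", CR %.2f, QS %.2f", attr(x, "cr"), attr(x, "qs")))
  cat("\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
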