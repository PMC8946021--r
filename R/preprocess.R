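# Segmentation front end shared by both acquisition schemes: classical
# fixed 300-sample framing for PSCCS, and RR-midpoint beat segmentation with
# resampling to 301 samples (plus reversible R-wave centring) for CPCS.

#' Detect R peaks (Pan-Tompkins-style)
#'
#' Band-pass (5-15 Hz, zero-phase Butterworth), differentiate, square, and
#' integrate over a 150 ms moving window; local maxima of the integrated
#' energy above an adaptive threshold are accepted under a 0.2 s refractory
#' period, then each detection is refined to the raw-signal maximum in a
#' +-110 ms window. The detector is deterministic. When the record carries
#' annotations and `use_annotations = TRUE`, the annotated indices are
#' returned verbatim instead (exact reproduction mode).
#'
#' @param record an [ecg_record()] with at least 1 s of signal.
#' @param use_annotations return annotated R indices when available.
#' @param refractory minimum distance between detections, seconds.
#' @param threshold_frac fraction of the high quantile of integrated energy
#'   used as detection threshold.
#' @return integer vector of strictly increasing 0-based sample indices
#'   (possibly empty).
#' @export
detect_r_peaks <- function(record, use_annotations = FALSE, refractory = 0.2,
                           threshold_frac = 0.1) {
  stopifnot(inherits(record, "ecg_record"))
  if (use_annotations && !is.null(record$annotations))
    return(as.integer(record$annotations$r_index))
  x <- record$samples
  fs <- record$fs
  if (length(x) <= fs)
    stop_cs("detect_r_peaks() needs more than 1 s of signal (%d samples at %g Hz)",
            length(x), fs, class = "cardiocs_bad_input")
  if (all(x == x[1])) return(integer(0))

  bf <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  bp <- signal::filtfilt(bf, x)
  der <- c(0, diff(bp))
  sq <- der^2
  w <- max(3L, as.integer(round(0.15 * fs)))
  mwi <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  mwi[is.na(mwi)] <- 0

  thr <- threshold_frac * stats::quantile(mwi, 0.99, names = FALSE)
  n <- length(mwi)
  is_max <- c(FALSE, mwi[2:(n - 1)] >= mwi[1:(n - 2)] &
                     mwi[2:(n - 1)] >= mwi[3:n], FALSE)
  cand <- which(is_max & mwi > thr & thr > 0)
  if (!length(cand)) return(integer(0))

  # refractory: greedy scan keeping the stronger of two close candidates
  ref <- as.integer(round(refractory * fs))
  keep <- integer(0)
  for (i in cand) {
    if (!length(keep) || i - keep[length(keep)] > ref) keep <- c(keep, i)
    else if (mwi[i] > mwi[keep[length(keep)]]) keep[length(keep)] <- i
  }

  # refine to the raw-signal maximum near each energy peak
  half_win <- as.integer(round(0.11 * fs))
  peaks <- vapply(keep, function(i) {
    lo <- max(1L, i - half_win); hi <- min(length(x), i + half_win)
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))
  peaks <- sort(unique(peaks))
  # merge refinements that collapsed onto near-identical raw maxima
  if (length(peaks) > 1L) peaks <- peaks[c(TRUE, diff(peaks) > ref)]
  as.integer(peaks - 1L)   # 0-based
}

#' Score a detection against ground truth
#'
#' Greedy one-to-one matching of detected to annotated indices within
#' `tol_s` seconds.
#'
#' @param detected,truth 0-based index vectors.
#' @param fs sampling frequency (Hz).
#' @param tol_s matching tolerance in seconds.
#' @return list with `tp`, `fp`, `fn`, `sensitivity`, `ppv`.
#' @export
score_detection <- function(detected, truth, fs, tol_s = 0.05) {
  tol <- tol_s * fs
  used <- logical(length(detected))
  tp <- 0L
  for (t in truth) {
    d <- which(!used & abs(detected - t) <= tol)
    if (length(d)) { used[d[which.min(abs(detected[d] - t))]] <- TRUE; tp <- tp + 1L }
  }
  fp <- sum(!used); fn <- length(truth) - tp
  list(tp = tp, fp = fp, fn = fn,
       sensitivity = if (length(truth)) tp / length(truth) else NA_real_,
       ppv = if (length(detected)) tp / length(detected) else NA_real_)
}

#' Cut a record into consecutive non-overlapping frames
#'
#' The first `frame_len` samples form the first frame, the next `frame_len`
#' the second, and so on; a trailing remainder shorter than `frame_len` is
#' discarded (with a message).
#'
#' @param record an [ecg_record()].
#' @param frame_len frame length in samples (default 300).
#' @return numeric matrix `frame_len x n_frames` with attributes
#'   `start_index` (0-based frame offsets) and `record_id`.
#' @export
frame_signal <- function(record, frame_len = 300L) {
  stopifnot(inherits(record, "ecg_record"))
  n <- length(record$samples)
  if (n < frame_len)
    stop_cs("record has %d samples, need at least frame_len = %d", n, frame_len,
            class = "cardiocs_bad_input")
  k <- n %/% frame_len
  dropped <- n - k * frame_len
  if (dropped > 0)
    message(sprintf("frame_signal: dropped %d trailing samples (< one frame)", dropped))
  m <- matrix(record$samples[seq_len(k * frame_len)], nrow = frame_len)
  attr(m, "start_index") <- (seq_len(k) - 1L) * as.integer(frame_len)
  attr(m, "record_id") <- record$record_id
  m
}

#' Cardiac-pattern container
#'
#' A single beat delimited by the midpoints of its two adjacent RR intervals
#' and resampled to a fixed 301 samples, with the metadata needed to reverse
#' both the resampling and any R-wave centring.
#'
#' @param x numeric vector, length 301.
#' @param r_index 0-based index of the R peak within `x`.
#' @param class_label optional integer beat class.
#' @param reversal list with `orig_start`, `orig_end`, `orig_r` (0-based raw
#'   sample bounds and R index) and, once centred, `left_len` / `right_len`.
#' @param centered logical; `TRUE` after [center_pattern()].
#' @param record_id source record.
#' @return object of class `cardiac_pattern`.
#' @export
cardiac_pattern <- function(x, r_index, class_label = NA_integer_,
                            reversal = list(), centered = FALSE,
                            record_id = "record") {
  if (length(x) != 301L)
    stop_cs("cardiac pattern must have 301 samples, got %d", length(x),
            class = "cardiocs_bad_input")
  structure(list(x = as.numeric(x), r_index = as.integer(r_index),
                 class_label = class_label, reversal = reversal,
                 centered = isTRUE(centered), record_id = record_id),
            class = "cardiac_pattern")
}

#' Segment a record into cardiac patterns at RR-interval midpoints
#'
#' Beat *i* spans the raw samples from the midpoint of the previous RR
#' interval to the midpoint of the next one, inclusive, and is resampled to
#' 301 samples. The first and last beats lack an adjacent half-interval and
#' are dropped. The R location inside the pattern is the raw R index mapped
#' through the affine span-to-[0, 300] map, rounded to the nearest integer.
#'
#' @param record an [ecg_record()].
#' @param r_peaks 0-based R indices; defaults to annotations when present,
#'   otherwise [detect_r_peaks()].
#' @return list of (uncentered) [cardiac_pattern()] objects; empty (with a
#'   warning) when fewer than 3 R peaks are available.
#' @export
segment_patterns <- function(record, r_peaks = NULL) {
  stopifnot(inherits(record, "ecg_record"))
  if (is.null(r_peaks))
    r_peaks <- detect_r_peaks(record, use_annotations = !is.null(record$annotations))
  r_peaks <- as.integer(r_peaks)
  if (length(r_peaks) < 3L) {
    warning("segment_patterns: fewer than 3 R peaks, no patterns produced")
    return(list())
  }
  ann <- record$annotations
  lapply(2:(length(r_peaks) - 1L), function(i) {
    lb <- (r_peaks[i - 1L] + r_peaks[i]) %/% 2L
    rb <- (r_peaks[i] + r_peaks[i + 1L]) %/% 2L
    seg <- record$samples[(lb:rb) + 1L]
    x <- resample_spline(seg, 301L)
    r_in <- as.integer(round((r_peaks[i] - lb) / (rb - lb) * 300))
    # the affine map rounds to the nearest sample; snap to the discrete peak
    # so centering puts the true maximum at the shared knot
    win <- max(0L, r_in - 2L):min(300L, r_in + 2L)
    r_in <- win[which.max(abs(x[win + 1L]))]
    lab <- NA_integer_
    if (!is.null(ann) && nrow(ann)) {
      j <- which.min(abs(ann$r_index - r_peaks[i]))
      if (abs(ann$r_index[j] - r_peaks[i]) <= 0.05 * record$fs)
        lab <- ann$class_label[j]
    }
    cardiac_pattern(x, r_index = r_in, class_label = lab,
                    reversal = list(orig_start = lb, orig_end = rb,
                                    orig_r = r_peaks[i]),
                    centered = FALSE, record_id = record$record_id)
  })
}

#' Center the R wave at the middle sample of a pattern
#'
#' Resamples the segment left of the R peak to 151 samples and the segment
#' right of it to 151 samples (sharing the R sample), yielding a 301-sample
#' pattern with the R peak at 0-based index 150 (sample 151 in 1-based
#' counting). The left/right lengths are stored so the operation can be
#' reversed by [uncenter_pattern()]. The amplitude at the R knot is
#' preserved exactly.
#'
#' @param p an uncentered [cardiac_pattern()] with `0 < r_index < 300`.
#' @return a centred `cardiac_pattern`.
#' @export
center_pattern <- function(p) {
  stopifnot(inherits(p, "cardiac_pattern"))
  if (p$centered) stop_cs("pattern is already centered", class = "cardiocs_bad_input")
  r <- p$r_index
  if (r <= 0L || r >= 300L)
    stop_cs("R peak at pattern boundary (index %d): centering is degenerate", r,
            class = "cardiocs_bad_input")
  left <- resample_spline(p$x[1:(r + 1L)], 151L)
  right <- resample_spline(p$x[(r + 1L):301L], 151L)
  rev <- p$reversal
  rev$left_len <- r + 1L
  rev$right_len <- 301L - r
  out <- cardiac_pattern(c(left, right[-1L]), r_index = 150L,
                         class_label = p$class_label, reversal = rev,
                         centered = TRUE, record_id = p$record_id)
  out$x[151L] <- p$x[r + 1L]  # exact knot preservation against FP round-off
  out
}

#' Undo R-wave centering
#'
#' Inverse of [center_pattern()]: the two 151-sample halves are resampled
#' back to their recorded original lengths, restoring a 301-sample pattern
#' with the R peak at its original index.
#'
#' @param p a centred [cardiac_pattern()] whose `reversal` metadata carries
#'   `left_len` and `right_len`.
#' @return an uncentred `cardiac_pattern`.
#' @export
uncenter_pattern <- function(p) {
  stopifnot(inherits(p, "cardiac_pattern"))
  if (!p$centered) stop_cs("pattern is not centered", class = "cardiocs_bad_input")
  L <- p$reversal$left_len; R <- p$reversal$right_len
  if (is.null(L) || is.null(R))
    stop_cs("centering metadata (left_len/right_len) missing: cannot reverse",
            class = "cardiocs_bad_input")
  left <- resample_spline(p$x[1:151L], L)
  right <- resample_spline(p$x[151L:301L], R)
  rev <- p$reversal; rev$left_len <- NULL; rev$right_len <- NULL
  out <- cardiac_pattern(c(left, right[-1L]), r_index = L - 1L,
                         class_label = p$class_label, reversal = rev,
                         centered = FALSE, record_id = p$record_id)
  out$x[L] <- p$x[151L]
  out
}

#' Resample a pattern back to its original raw span
#'
#' Uses the reversal metadata recorded at segmentation to map a (possibly
#' reconstructed) 301-sample pattern back onto its original raw sample span.
#'
#' @param p an uncentred [cardiac_pattern()] (or a numeric length-301 vector
#'   plus explicit `span_len`).
#' @param span_len raw span length; defaults to the recorded bounds.
#' @return numeric vector of length `span_len`.
#' @export
pattern_to_raw <- function(p, span_len = NULL) {
  if (inherits(p, "cardiac_pattern")) {
    if (p$centered) p <- uncenter_pattern(p)
    span_len <- span_len %||% (p$reversal$orig_end - p$reversal$orig_start + 1L)
    x <- p$x
  } else x <- p
  if (is.null(span_len)) stop_cs("span_len required", class = "cardiocs_bad_input")
  resample_spline(x, span_len)
}
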