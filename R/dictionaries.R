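# The three dictionary families: raw-frame patient dictionaries (300-sample
# atoms), pattern-based patient dictionaries, the class-balanced universal
# mega-dictionary, and per-class (pathology-specific) dictionaries
# (301-sample atoms, with or without R-wave centring). Atoms used to build a
# dictionary are recorded so tests can hold them out.

#' Dictionary container
#'
#' Columns of `atoms` are the candidate signal components; `meta` carries one
#' row per atom (`class_label`, `record_id`, `source_index`). Atoms are
#' l2-normalized by default (better-conditioned basis pursuit; the
#' reconstruction stays on the original amplitude scale since the
#' coefficients absorb the norms). Flat (zero-norm) atoms are rejected.
#'
#' @param atoms numeric matrix, `frame_length x n_atoms`.
#' @param meta data.frame with `n_atoms` rows.
#' @param kind one of `"patient_raw"`, `"patient_pattern"`, `"mega"`,
#'   `"class_specific"`.
#' @param normalize scale every atom to unit Euclidean norm.
#' @param consumed bookkeeping about which part of the source the atoms
#'   consumed (prefix length, beat indices, sampled pattern ids).
#' @return object of class `cs_dictionary`.
#' @export
cs_dictionary <- function(atoms, meta = NULL, kind = "patient_raw",
                          normalize = TRUE, consumed = list()) {
  atoms <- as.matrix(atoms)
  if (is.null(meta))
    meta <- data.frame(class_label = NA_integer_, record_id = NA_character_,
                       source_index = seq_len(ncol(atoms)))
  stopifnot(nrow(meta) == ncol(atoms))
  norms <- sqrt(colSums(atoms^2))
  if (any(norms <= .EPS)) {
    bad <- which(norms <= .EPS)[1]
    stop_cs("atom %d has (near-)zero norm; flat atoms cannot be normalized", bad,
            class = "cardiocs_bad_input")
  }
  if (normalize) atoms <- sweep(atoms, 2, norms, "/")
  structure(list(atoms = atoms, meta = meta, kind = kind,
                 normalized = isTRUE(normalize), norms = norms,
                 consumed = consumed),
            class = "cs_dictionary")
}

#' @export
print.cs_dictionary <- function(x, ...) {
  cat(sprintf("<cs_dictionary %s> %d x %d atoms%s\n", x$kind,
              dict_frame_length(x), n_atoms(x),
              if (x$normalized) " (unit-norm)" else ""))
  cl <- x$meta$class_label
  if (!all(is.na(cl)))
    cat("  per-class counts:", paste(sprintf("%s:%d", names(table(cl)), table(cl)),
                                     collapse = " "), "\n")
  invisible(x)
}

#' @rdname cs_dictionary
#' @param dict a `cs_dictionary`.
#' @export
n_atoms <- function(dict) ncol(dict$atoms)

#' @rdname cs_dictionary
#' @export
dict_frame_length <- function(dict) nrow(dict$atoms)

dict_id <- function(dict) {
  sprintf("%s-%dx%d-%.10e", dict$kind, dict_frame_length(dict), n_atoms(dict),
          sum(dict$atoms^2))
}

#' Patient-specific raw-frame dictionary
#'
#' The first `n_atoms` consecutive non-overlapping `frame_len`-sample
#' segments of the record become the atoms, without any beat detection or
#' alignment (the R wave may fall anywhere in an atom, or be missing). The
#' consumed prefix length is recorded so evaluation uses only the remainder
#' of the record. With the defaults this consumes 210,000 samples, about the
#' first 10 minutes at 360 Hz.
#'
#' @param record an [ecg_record()].
#' @param n_atoms number of atoms (default 700).
#' @param frame_len atom length (default 300).
#' @param normalize l2-normalize atoms.
#' @return a `cs_dictionary` of kind `"patient_raw"`;
#'   `$consumed$prefix_samples` gives the dictionary prefix length.
#' @export
build_patient_raw <- function(record, n_atoms = 700L, frame_len = 300L,
                              normalize = TRUE) {
  stopifnot(inherits(record, "ecg_record"))
  need <- as.integer(n_atoms) * as.integer(frame_len)
  if (length(record$samples) < need)
    stop_cs("record '%s' has %d samples; %d atoms of %d samples need %d",
            record$record_id, length(record$samples), n_atoms, frame_len, need,
            class = "cardiocs_bad_input")
  atoms <- matrix(record$samples[seq_len(need)], nrow = frame_len)
  meta <- data.frame(class_label = NA_integer_, record_id = record$record_id,
                     source_index = seq_len(n_atoms))
  cs_dictionary(atoms, meta, "patient_raw", normalize,
                consumed = list(prefix_samples = need))
}

#' Patient-specific cardiac-pattern dictionary
#'
#' Atoms are the patient's first `n_beats` cardiac patterns (RR-midpoint
#' segmented, 301 samples, optionally R-wave centred). The indices of the
#' consumed patterns are recorded for test-set exclusion.
#'
#' @param record an [ecg_record()].
#' @param n_beats number of beats/atoms (default 700).
#' @param centered centre the R wave of every atom.
#' @param r_peaks optional explicit R indices (0-based).
#' @param normalize l2-normalize atoms.
#' @return a `cs_dictionary` of kind `"patient_pattern"`;
#'   `$consumed$pattern_indices` lists the consumed pattern positions.
#' @export
build_patient_patterns <- function(record, n_beats = 700L, centered = FALSE,
                                   r_peaks = NULL, normalize = TRUE) {
  pats <- segment_patterns(record, r_peaks)
  if (length(pats) < n_beats)
    stop_cs("record '%s' yields %d patterns; %d required", record$record_id,
            length(pats), n_beats, class = "cardiocs_bad_input")
  use <- pats[seq_len(n_beats)]
  if (centered) use <- lapply(use, center_pattern)
  atoms <- vapply(use, function(p) p$x, numeric(301L))
  meta <- data.frame(class_label = vapply(use, function(p) as.integer(p$class_label), integer(1)),
                     record_id = record$record_id,
                     source_index = seq_len(n_beats))
  cs_dictionary(atoms, meta, "patient_pattern", normalize,
                consumed = list(pattern_indices = seq_len(as.integer(n_beats)),
                                centered = centered))
}

patterns_to_matrix <- function(patterns) {
  vapply(patterns, function(p) if (inherits(p, "cardiac_pattern")) p$x else as.numeric(p),
         numeric(301L))
}

#' Group cardiac patterns by class label
#'
#' @param patterns list of [cardiac_pattern()] with class labels.
#' @return named list (classes "1".."8" present in the input) of pattern
#'   lists.
#' @export
split_patterns_by_class <- function(patterns) {
  labs <- vapply(patterns, function(p) as.integer(p$class_label), integer(1))
  if (anyNA(labs)) stop_cs("all patterns must carry class labels", class = "cardiocs_bad_input")
  split(patterns, labs)
}

#' Universal (mega) dictionary
#'
#' Samples `per_class` patterns per class uniformly without replacement
#' (seeded) and pools them into one class-balanced dictionary — with the
#' defaults 184 atoms from each of the 8 classes, 1472 atoms in total. The
#' sampled identities are recorded so the same patterns are excluded from
#' test sets.
#'
#' @param patterns_by_class named list of per-class pattern lists (or
#'   301-row matrices), as from [split_patterns_by_class()].
#' @param per_class atoms drawn per class (default 184).
#' @param seed selection seed.
#' @param normalize l2-normalize atoms.
#' @return a `cs_dictionary` of kind `"mega"`; `$consumed$selected` is a
#'   named list of the drawn per-class indices.
#' @export
build_mega <- function(patterns_by_class, per_class = 184L, seed = 0L,
                       normalize = TRUE) {
  classes <- names(patterns_by_class)
  mats <- lapply(patterns_by_class, function(p)
    if (is.matrix(p)) p else patterns_to_matrix(p))
  for (cl in classes)
    if (ncol(mats[[cl]]) < per_class)
      stop_cs("class %s supplies %d patterns, need %d", cl, ncol(mats[[cl]]),
              per_class, class = "cardiocs_bad_input")
  sel <- with_seed(seed, lapply(mats, function(m) sort(sample.int(ncol(m), per_class))))
  atoms <- do.call(cbind, lapply(classes, function(cl) mats[[cl]][, sel[[cl]], drop = FALSE]))
  meta <- data.frame(
    class_label = rep(as.integer(classes), each = per_class),
    record_id = NA_character_,
    source_index = unlist(sel, use.names = FALSE))
  cs_dictionary(atoms, meta, "mega", normalize,
                consumed = list(selected = sel, per_class = as.integer(per_class)))
}

#' Pathology-specific dictionaries
#'
#' One dictionary per class, each with `n_atoms` single-class atoms drawn
#' uniformly without replacement (seeded).
#'
#' @inheritParams build_mega
#' @param n_atoms atoms per class dictionary (default 700).
#' @return named list of `cs_dictionary` objects of kind
#'   `"class_specific"`, one per class.
#' @export
build_class_dictionaries <- function(patterns_by_class, n_atoms = 700L,
                                     seed = 0L, normalize = TRUE) {
  classes <- names(patterns_by_class)
  mats <- lapply(patterns_by_class, function(p)
    if (is.matrix(p)) p else patterns_to_matrix(p))
  for (cl in classes)
    if (ncol(mats[[cl]]) < n_atoms)
      stop_cs("class %s supplies %d patterns, need %d", cl, ncol(mats[[cl]]),
              n_atoms, class = "cardiocs_bad_input")
  sels <- with_seed(seed, lapply(mats, function(m) sort(sample.int(ncol(m), n_atoms))))
  out <- lapply(classes, function(cl) {
    meta <- data.frame(class_label = as.integer(cl), record_id = NA_character_,
                       source_index = sels[[cl]])
    cs_dictionary(mats[[cl]][, sels[[cl]], drop = FALSE], meta, "class_specific",
                  normalize, consumed = list(selected = sels[[cl]]))
  })
  names(out) <- classes
  out
}
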