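# End-to-end pipelines. PSCCS: raw 300-sample frames, patient-specific raw
# dictionary from the record prefix, remainder of the record as test
# material. CPCS: RR-midpoint cardiac patterns (optionally R-wave centred)
# reconstructed against a mega-dictionary, a classifier-selected
# pathology-specific dictionary, or a patient-specific pattern dictionary.
# Every run enforces train/test disjointness and that reconstruction uses
# the sensing matrix recorded at acquisition.

#' Run the patient-specific classical CS pipeline
#'
#' Builds a raw-frame dictionary from the record prefix, frames the rest of
#' the signal into consecutive 300-sample vectors, compresses each with the
#' requested sensing matrix and reconstructs by basis pursuit.
#'
#' @param record an [ecg_record()] long enough for the dictionary prefix
#'   plus at least one test frame.
#' @param cr_label compression-ratio label (4, 10 or 15).
#' @param matrix_kind `"gaussian"`, `"bernoulli"` or `"optimized"`.
#' @param n_atoms dictionary atoms (default 700).
#' @param frame_len frame length (default 300).
#' @param n_test_frames cap on the number of test frames (`NULL` = all).
#' @param seed seed for the sensing matrix (and atom selection when
#'   optimized).
#' @param tol basis-pursuit feasibility tolerance.
#' @param relaxed use the inexact basis-pursuit mode (for noisy records).
#' @return list of class `psccs_result`: `report` (per-frame
#'   [distortion_report()]), `summary` ([aggregate_reports()]),
#'   `reconstructed` (test frames re-concatenated), `phi`, `dict`.
#' @export
run_psccs <- function(record, cr_label = 15, matrix_kind = "gaussian",
                      n_atoms = 700L, frame_len = 300L, n_test_frames = NULL,
                      seed = 0L, tol = 1e-8, relaxed = FALSE) {
  stopifnot(inherits(record, "ecg_record"))
  dict <- build_patient_raw(record, n_atoms = n_atoms, frame_len = frame_len)
  prefix <- dict$consumed$prefix_samples
  rest <- record$samples[-seq_len(prefix)]
  if (length(rest) < frame_len)
    stop_cs("record '%s' has no test material beyond the %d-sample dictionary prefix",
            record$record_id, prefix, class = "cardiocs_bad_input")
  test_rec <- ecg_record(rest, fs = record$fs, bits_per_sample = record$bits_per_sample,
                         record_id = record$record_id)
  frames <- suppressMessages(frame_signal(test_rec, frame_len))
  if (!is.null(n_test_frames)) frames <- frames[, seq_len(min(n_test_frames, ncol(frames))), drop = FALSE]

  m <- measurements_for_cr(frame_len, cr_label)
  phi <- make_projection(matrix_kind, m, frame_len, seed = seed, dict = dict)
  cr <- compression_ratio(frame_len, m, record$bits_per_sample, record$bits_per_sample)

  recon <- matrix(NA_real_, frame_len, ncol(frames))
  pv <- pnv <- numeric(ncol(frames))
  for (j in seq_len(ncol(frames))) {
    x <- frames[, j]
    y <- compress(x, phi, source_id = sprintf("%s/frame%d", record$record_id, j))
    code <- basis_pursuit(y, phi, dict, tol = tol, relaxed = relaxed)
    xh <- reconstruct(code, dict)
    recon[, j] <- xh
    pv[j] <- prd(x, xh)
    pnv[j] <- prdn(x, xh)
  }
  report <- distortion_report(seq_len(ncol(frames)), pv, pnv, cr, record$record_id)
  structure(list(report = report, summary = aggregate_reports(report),
                 reconstructed = as.numeric(recon), phi = phi, dict = dict,
                 cr_label = cr_label, matrix_kind = matrix_kind),
            class = "psccs_result")
}

# reconstruct one pattern against `dict`, de-centring if asked, and score it
# against the reference (uncentred) pattern
.cpcs_score_one <- function(p_ref, x_in, phi, dict, tol, decenter, center) {
  y <- compress(x_in, phi)
  code <- basis_pursuit(y, phi, dict, tol = tol)
  xh <- reconstruct(code, dict)
  if (center && decenter) {
    ph <- cardiac_pattern(xh, 150L, reversal = c(p_ref$reversal,
                                                 list(left_len = p_ref$r_index + 1L,
                                                      right_len = 301L - p_ref$r_index)),
                          centered = TRUE)
    xh <- uncenter_pattern(ph)$x
    ref <- p_ref$x
  } else if (center) {
    ref <- x_in
  } else {
    ref <- p_ref$x
  }
  list(xhat = xh, ref = ref, code = code)
}

#' Run the cardiac-pattern CS pipeline
#'
#' Segments the record into 301-sample cardiac patterns, optionally centres
#' the R wave, and reconstructs held-out test patterns against
#' * `branch = "mega"`: the class-balanced mega-dictionary (with alpha-max
#'   class estimates as a by-product),
#' * `branch = "specific"`: the pathology-specific dictionary selected per
#'   beat by the configured classifier (`"alpha_max"`, `"knn"`, `"mlp"`, or
#'   `"oracle"` for ground-truth labels); unclassifiable beats fall back to
#'   the mega-dictionary (logged),
#' * `branch = "patient"`: a patient-specific pattern dictionary built from
#'   the record's first beats.
#'
#' Dictionaries are built from the record's own labelled patterns with the
#' drawn atoms excluded from the test set; prebuilt dictionaries can be
#' supplied instead. When `center = TRUE` and `decenter = TRUE` the
#' reconstruction is de-centred with the stored stretch ratios before
#' scoring against the uncentred original.
#'
#' @inheritParams run_psccs
#' @param branch `"mega"`, `"specific"` or `"patient"`.
#' @param center centre the R wave of atoms and test patterns.
#' @param classifier class selector for the specific branch (`NULL` is a
#'   configuration error there).
#' @param per_class mega-dictionary atoms per class (default 184).
#' @param class_dict_atoms atoms per pathology-specific dictionary
#'   (default 700).
#' @param patient_dict_beats beats consumed by the patient branch's
#'   dictionary (default 700).
#' @param n_test_per_class held-out test patterns per class (default 200);
#'   for the patient branch, total test beats.
#' @param mega,class_dicts optional prebuilt dictionaries (when supplied,
#'   test patterns are all of the record's patterns).
#' @param k KNN neighbour count.
#' @param decenter de-centre reconstructions before scoring.
#' @return list of class `cpcs_result`: `report`, `summary`, `classes`
#'   (data.frame truth/predicted for classifying branches), `confusion`,
#'   `phi`, plus the dictionaries used.
#' @export
run_cpcs <- function(record, cr_label = 15, matrix_kind = "gaussian",
                     branch = c("mega", "specific", "patient"),
                     center = TRUE, classifier = "alpha_max",
                     per_class = 184L, class_dict_atoms = 700L,
                     patient_dict_beats = 700L, n_test_per_class = 200L,
                     mega = NULL, class_dicts = NULL, k = 1L,
                     seed = 0L, tol = 1e-8, decenter = TRUE) {
  branch <- match.arg(branch)
  stopifnot(inherits(record, "ecg_record"))
  if (branch == "specific" && is.null(classifier))
    stop_cs("the pathology-specific branch needs a classifier (alpha_max, knn, mlp or oracle)",
            class = "cardiocs_bad_input")

  patterns <- segment_patterns(record)
  if (!length(patterns))
    stop_cs("record '%s' yields no cardiac patterns", record$record_id,
            class = "cardiocs_bad_input")
  N <- 301L
  m <- measurements_for_cr(N, cr_label)
  cr <- compression_ratio(N, m, record$bits_per_sample, record$bits_per_sample)

  if (branch == "patient") {
    dict <- build_patient_patterns(record, n_beats = patient_dict_beats,
                                   centered = center)
    test_idx <- setdiff(seq_along(patterns), dict$consumed$pattern_indices)
    test_idx <- utils::head(test_idx, n_test_per_class)
    test <- patterns[test_idx]
    phi <- make_projection(matrix_kind, m, N, seed = seed, dict = dict)
    rows <- lapply(seq_along(test), function(j) {
      p <- test[[j]]
      x_in <- if (center) center_pattern(p)$x else p$x
      sc <- .cpcs_score_one(p, x_in, phi, dict, tol, decenter, center)
      data.frame(frame_id = j, prd = prd(sc$ref, sc$xhat), prdn = prdn(sc$ref, sc$xhat))
    })
    df <- do.call(rbind, rows)
    report <- distortion_report(df$frame_id, df$prd, df$prdn, cr, record$record_id)
    return(structure(list(report = report, summary = aggregate_reports(report),
                          classes = NULL, confusion = NULL, phi = phi,
                          dict = dict, branch = branch, cr_label = cr_label,
                          matrix_kind = matrix_kind),
                     class = "cpcs_result"))
  }

  by_class <- split_patterns_by_class(patterns)
  prepped <- if (center) lapply(by_class, function(ps) lapply(ps, center_pattern)) else by_class

  held_out <- lapply(names(by_class), function(cl) seq_along(by_class[[cl]]))
  names(held_out) <- names(by_class)
  if (is.null(mega)) {
    mega <- build_mega(prepped, per_class = per_class, seed = seed)
    held_out <- lapply(names(by_class), function(cl)
      setdiff(held_out[[cl]], mega$consumed$selected[[cl]]))
    names(held_out) <- names(by_class)
  }
  if (branch == "specific" && is.null(class_dicts)) {
    class_dicts <- build_class_dictionaries(prepped, n_atoms = class_dict_atoms,
                                            seed = seed + 1L)
    held_out <- lapply(names(by_class), function(cl)
      setdiff(held_out[[cl]], class_dicts[[cl]]$consumed$selected))
    names(held_out) <- names(by_class)
  }

  test_sets <- with_seed(seed + 2L, lapply(names(by_class), function(cl) {
    pool <- held_out[[cl]]
    if (!length(pool))
      stop_cs("class %s has no held-out patterns left for testing", cl,
              class = "cardiocs_bad_input")
    sort(sample(pool, min(n_test_per_class, length(pool))))
  }))
  names(test_sets) <- names(by_class)

  phi <- make_projection(matrix_kind, m, N, seed = seed, dict = mega)

  knn_model <- if (branch == "specific" && identical(classifier, "knn"))
    knn_fit(mega, phi, k = k, mode = "compressed") else NULL
  mlp_model <- if (branch == "specific" && identical(classifier, "mlp")) {
    atoms <- sweep(mega$atoms, 2, mega$norms, "*")
    mlp_fit(t(phi$phi %*% atoms), mega$meta$class_label, seed = seed,
            phi_id = phi_id(phi))
  } else NULL

  truth <- integer(0); pred <- integer(0)
  pv <- pnv <- numeric(0); fid <- character(0)
  n_fallback <- 0L
  for (cl in names(by_class)) {
    for (idx in test_sets[[cl]]) {
      p <- by_class[[cl]][[idx]]
      x_in <- if (center) center_pattern(p)$x else p$x
      y <- compress(x_in, phi)

      use_dict <- mega
      p_hat <- NA_integer_
      if (branch == "specific") {
        p_hat <- switch(classifier,
          oracle = as.integer(cl),
          knn = knn_predict(knn_model, y),
          mlp = mlp_predict(mlp_model, y$y),
          alpha_max = classify_alpha_max(basis_pursuit(y, phi, mega, tol = tol), mega),
          stop_cs("unknown classifier '%s'", classifier, class = "cardiocs_bad_input"))
        if (!is.na(p_hat) && as.character(p_hat) %in% names(class_dicts)) {
          use_dict <- class_dicts[[as.character(p_hat)]]
        } else {
          n_fallback <- n_fallback + 1L
          use_dict <- mega
        }
      }
      sc <- .cpcs_score_one(p, x_in, phi, use_dict, tol, decenter, center)
      if (branch == "mega")
        p_hat <- classify_alpha_max(sc$code, mega)
      truth <- c(truth, as.integer(cl)); pred <- c(pred, p_hat)
      pv <- c(pv, prd(sc$ref, sc$xhat)); pnv <- c(pnv, prdn(sc$ref, sc$xhat))
      fid <- c(fid, sprintf("c%s/%d", cl, idx))
    }
  }
  if (n_fallback > 0)
    message(sprintf("run_cpcs: %d beat(s) fell back to the mega-dictionary", n_fallback))

  report <- distortion_report(fid, pv, pnv, cr, record$record_id)
  structure(list(report = report, summary = aggregate_reports(report),
                 classes = data.frame(truth = truth, predicted = pred),
                 confusion = confusion_matrix(truth, pred, classes = sort(unique(truth))),
                 phi = phi, mega = mega, class_dicts = class_dicts,
                 branch = branch, cr_label = cr_label, matrix_kind = matrix_kind,
                 accuracy = mean(truth == pred, na.rm = TRUE)),
            class = "cpcs_result")
}

#' Summary grid at the 15:1 compression label
#'
#' Runs the full grid of three sensing matrices against six
#' dictionary/preprocessing settings (classical patient-specific raw frames;
#' mega-dictionary without and with R-wave centring; pathology-specific
#' without and with centring; patient-specific patterns with centring) and
#' tabulates average PRD, PRDN and QS per cell. Failures in a cell are
#' recorded (`NA` metrics) and the grid continues.
#'
#' @param records a list of [ecg_record()] (or a single record).
#' @param cr_label compression label, default 15.
#' @param seeds one seed per record (recycled).
#' @param classifier classifier for the specific settings.
#' @param ... sizing arguments passed on to [run_psccs()]/[run_cpcs()]
#'   (`n_atoms`, `per_class`, `class_dict_atoms`, `patient_dict_beats`,
#'   `n_test_per_class`, `n_test_frames`, ...).
#' @return data.frame with columns `setting`, `matrix`, `cr`, `avg_prd`,
#'   `avg_prdn`, `qs` (18 rows).
#' @export
run_table9 <- function(records, cr_label = 15, seeds = 0L,
                       classifier = "oracle", ...) {
  if (inherits(records, "ecg_record")) records <- list(records)
  seeds <- rep_len(seeds, length(records))
  matrices <- c("optimized", "bernoulli", "gaussian")
  settings <- list(
    list(id = "psccs_raw",        fun = "psccs", center = FALSE),
    list(id = "mega",             fun = "cpcs", branch = "mega", center = FALSE),
    list(id = "mega_centered",    fun = "cpcs", branch = "mega", center = TRUE),
    list(id = "specific",         fun = "cpcs", branch = "specific", center = FALSE),
    list(id = "specific_centered",fun = "cpcs", branch = "specific", center = TRUE),
    list(id = "patient_centered", fun = "cpcs", branch = "patient", center = TRUE))
  dots <- list(...)
  psccs_extra <- dots[names(dots) %in% names(formals(run_psccs))]
  cpcs_extra <- dots[names(dots) %in% names(formals(run_cpcs))]
  rows <- list()
  for (s in settings) for (mk in matrices) {
    sums <- lapply(seq_along(records), function(i) {
      tryCatch({
        res <- if (s$fun == "psccs")
          do.call(run_psccs, c(list(records[[i]], cr_label = cr_label,
                                    matrix_kind = mk, seed = seeds[i]),
                               psccs_extra))
        else
          do.call(run_cpcs, c(list(records[[i]], cr_label = cr_label,
                                   matrix_kind = mk, branch = s$branch,
                                   center = s$center, classifier = classifier,
                                   seed = seeds[i]),
                              cpcs_extra))
        res$report
      }, error = function(e) {
        warning(sprintf("run_table9: %s/%s on record %d failed: %s",
                        s$id, mk, i, conditionMessage(e)))
        NULL
      })
    })
    ok <- !vapply(sums, is.null, logical(1))
    if (any(ok)) {
      agg <- aggregate_reports(sums[ok])
      rows[[length(rows) + 1L]] <- data.frame(
        setting = s$id, matrix = mk, cr = attr(agg, "cr"),
        avg_prd = attr(agg, "avg_prd"), avg_prdn = attr(agg, "avg_prdn"),
        qs = attr(agg, "qs"))
    } else {
      rows[[length(rows) + 1L]] <- data.frame(setting = s$id, matrix = mk,
                                              cr = NA_real_, avg_prd = NA_real_,
                                              avg_prdn = NA_real_, qs = NA_real_)
    }
  }
  do.call(rbind, rows)
}
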