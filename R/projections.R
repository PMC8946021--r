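# The three sensing-matrix families: Gaussian i.i.d., symmetric 0/1
# Bernoulli (each row mirror-symmetric), and the dictionary-optimized
# product Phi_0 %*% t(D) with D a random square selection of atoms.

projection_matrix <- function(phi, kind, seed, dict_ref = NULL) {
  structure(list(phi = phi, kind = kind, seed = as.integer(seed),
                 dict_ref = dict_ref, m = nrow(phi), n = ncol(phi)),
            class = "projection_matrix")
}

#' @export
print.projection_matrix <- function(x, ...) {
  cat(sprintf("<projection_matrix %s> %d x %d, seed %d%s\n", x$kind, x$m, x$n,
              x$seed, if (!is.null(x$dict_ref)) paste0(", dict ", x$dict_ref) else ""))
  invisible(x)
}

phi_id <- function(phi) {
  sprintf("%s-%d-%dx%d-%.10e", phi$kind, phi$seed, phi$m, phi$n, sum(phi$phi^2))
}

check_compressive <- function(m, N) {
  if (m <= 0 || N <= 0) stop_cs("m and N must be positive", class = "cardiocs_bad_input")
  if (m >= N) stop_cs("sensing must be compressive: m = %d >= N = %d", m, N,
                      class = "cardiocs_bad_input")
}

#' Gaussian random sensing matrix
#'
#' `m x N` matrix of i.i.d. standard-normal entries. Rows are the sampling
#' vectors; no rescaling is applied.
#'
#' @param m number of measurements (rows), `0 < m < N`.
#' @param N signal length (columns).
#' @param seed integer seed.
#' @return a `projection_matrix` of kind `"gaussian"`.
#' @export
gaussian_matrix <- function(m, N, seed = 0L) {
  check_compressive(m, N)
  phi <- with_seed(seed, matrix(stats::rnorm(m * N), nrow = m))
  projection_matrix(phi, "gaussian", seed)
}

#' Symmetric Bernoulli 0/1 sensing matrix
#'
#' Each row's first half is drawn i.i.d. Bernoulli(p) in \{0, 1\} and the
#' second half mirrors it (`row[N - 1 - j] = row[j]`); for odd `N` the
#' center entry belongs to the generated half. Rows that come out all zero
#' are redrawn. Entries are used as-is (no centring or scaling).
#'
#' @inheritParams gaussian_matrix
#' @param p Bernoulli success probability, default 0.5.
#' @return a `projection_matrix` of kind `"bernoulli_sym"`.
#' @export
bernoulli_symmetric_matrix <- function(m, N, seed = 0L, p = 0.5) {
  check_compressive(m, N)
  half <- as.integer(ceiling(N / 2))
  phi <- with_seed(seed, {
    draw_row <- function() {
      for (attempt in 1:100) {
        h <- stats::rbinom(half, 1L, p)
        row <- numeric(N)
        row[seq_len(half)] <- h
        row[N:(N - half + 1L)][seq_len(half)] <- h  # mirror (center shared for odd N)
        if (any(row != 0)) return(row)
        if (p == 0) break
      }
      stop_cs("could not draw a nonzero Bernoulli row (p = %g)", p,
              class = "cardiocs_bad_input")
    }
    t(vapply(seq_len(m), function(i) draw_row(), numeric(N)))
  })
  projection_matrix(phi, "bernoulli_sym", seed)
}

#' Dictionary-optimized sensing matrix
#'
#' Products the base random matrix with the transpose of a square matrix `D`
#' whose columns are `N` distinct dictionary atoms chosen uniformly at
#' random: `phi_out = phi_base %*% t(D)`. Adapting the rows to the
#' dictionary's span lowers reconstruction error for signals sparse in that
#' dictionary.
#'
#' @param base a `projection_matrix` (typically Gaussian), `base$n` must
#'   equal the dictionary frame length.
#' @param dict a [cs_dictionary] with at least `N` atoms.
#' @param seed seed for the atom selection.
#' @return a `projection_matrix` of kind `"dict_optimized"` with `dict_ref`
#'   recording the dictionary used.
#' @export
optimized_matrix <- function(base, dict, seed = 0L) {
  stopifnot(inherits(base, "projection_matrix"), inherits(dict, "cs_dictionary"))
  N <- base$n
  if (dict_frame_length(dict) != N)
    stop_cs("dictionary frame length %d != base N = %d", dict_frame_length(dict), N,
            class = "cardiocs_bad_input")
  if (n_atoms(dict) < N)
    stop_cs("need at least N = %d atoms for optimization, dictionary has %d",
            N, n_atoms(dict), class = "cardiocs_bad_input")
  phi <- with_seed(seed, {
    res <- NULL
    for (attempt in 1:2) {
      sel <- sort(sample.int(n_atoms(dict), N))
      D <- dict$atoms[, sel, drop = FALSE]
      if (rcond(D) > 1e-14) { res <- base$phi %*% t(D); break }
    }
    if (is.null(res))
      stop_cs("selected atom matrix singular to working precision (twice)",
              class = "cardiocs_numeric")
    res
  })
  projection_matrix(phi, "dict_optimized", seed, dict_ref = dict_id(dict))
}

#' Measurement count for a labelled compression ratio
#'
#' The conventional labels 4:1, 10:1 and 15:1 correspond, for 300-sample
#' frames, to m = 75, 30 and 20 rows; for 301-sample patterns the same row
#' counts are used (so the realized bit-level CR of the 15:1 label is
#' 301/20 = 15.05).
#'
#' @param N frame length.
#' @param cr_label numeric label (4, 10 or 15, though any positive value
#'   works).
#' @return integer number of measurements `round(N / cr_label)`.
#' @export
measurements_for_cr <- function(N, cr_label) {
  if (cr_label <= 1) stop_cs("cr_label must exceed 1", class = "cardiocs_bad_input")
  as.integer(round(N / cr_label))
}

#' Build a sensing matrix by kind
#'
#' Convenience dispatcher used by the pipelines.
#'
#' @param kind `"gaussian"`, `"bernoulli"`/`"bernoulli_sym"`, or
#'   `"optimized"`/`"dict_optimized"`.
#' @param m,N dimensions.
#' @param seed seed.
#' @param dict dictionary (required for the optimized kind).
#' @return a `projection_matrix`.
#' @export
make_projection <- function(kind, m, N, seed = 0L, dict = NULL) {
  kind <- match.arg(kind, c("gaussian", "bernoulli", "bernoulli_sym",
                            "optimized", "dict_optimized"))
  switch(kind,
    gaussian = gaussian_matrix(m, N, seed),
    bernoulli = ,
    bernoulli_sym = bernoulli_symmetric_matrix(m, N, seed),
    optimized = ,
    dict_optimized = {
      if (is.null(dict))
        stop_cs("optimized sensing matrix needs a dictionary", class = "cardiocs_bad_input")
      optimized_matrix(gaussian_matrix(m, N, seed), dict, seed = seed + 1L)
    })
}
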