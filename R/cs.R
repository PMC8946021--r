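# Compressive acquisition y = Phi x and basis-pursuit reconstruction:
# alpha_hat = argmin ||alpha||_1 s.t. y = Phi Psi alpha, x_hat = Psi alpha_hat.

#' Compressively acquire a frame or cardiac pattern
#'
#' Computes `y = Phi x`. The returned measurements remember which sensing
#' matrix produced them, so reconstruction can verify it uses the same one.
#'
#' @param x numeric vector of length `phi$n` (a 300-sample frame or a
#'   301-sample pattern), or a [cardiac_pattern()].
#' @param phi a `projection_matrix`.
#' @param source_id identifier carried along for reporting.
#' @return object of class `cs_measurements` with fields `y`, `phi_id`,
#'   `source_id`.
#' @export
compress <- function(x, phi, source_id = "frame") {
  stopifnot(inherits(phi, "projection_matrix"))
  if (inherits(x, "cardiac_pattern")) x <- x$x
  x <- as.numeric(x)
  if (length(x) != phi$n)
    stop_cs("signal length %d does not match sensing matrix N = %d",
            length(x), phi$n, class = "cardiocs_bad_input")
  structure(list(y = drop(phi$phi %*% x), phi_id = phi_id(phi),
                 source_id = source_id),
            class = "cs_measurements")
}

#' Basis-pursuit sparse coding
#'
#' Solves the equality-constrained l1 problem
#' `min ||alpha||_1  s.t.  y = (Phi Psi) alpha`
#' as a linear program over the split `alpha = alpha_plus - alpha_minus`
#' (both non-negative), with a Mehrotra predictor-corrector interior-point
#' method. Measurement noise is not modelled in this default mode; a relaxed
#' mode (`relaxed = TRUE`) replaces the equality with the box
#' `|y_i - (Theta alpha)_i| <= epsilon / sqrt(m)` for all `i` (which implies
#' `||y - Theta alpha||_2 <= epsilon`), useful for noisy real recordings.
#'
#' @param y a `cs_measurements` object (or bare numeric vector of length
#'   `phi$m`).
#' @param phi the `projection_matrix` used at acquisition; when `y` carries a
#'   `phi_id` it must match.
#' @param dict the reconstruction dictionary (frame length must equal
#'   `phi$n`).
#' @param tol feasibility tolerance: on success the returned
#'   `residual_norm <= tol * max(1, ||y||)`.
#' @param relaxed use the inexact-constraint mode.
#' @param epsilon l2 radius for the relaxed mode; default `1e-6 * ||y||`.
#' @param max_iter interior-point iteration cap.
#' @return object of class `sparse_code`: `alpha` (length `n_atoms`),
#'   `dict_id`, `residual_norm`, `objective` (= `sum(abs(alpha))`),
#'   `iterations`, `status`.
#' @export
basis_pursuit <- function(y, phi, dict, tol = 1e-8, relaxed = FALSE,
                          epsilon = NULL, max_iter = 200L) {
  stopifnot(inherits(phi, "projection_matrix"), inherits(dict, "cs_dictionary"))
  if (inherits(y, "cs_measurements")) {
    if (!identical(y$phi_id, phi_id(phi)))
      stop_cs("measurements were acquired under a different sensing matrix (%s)",
              y$phi_id, class = "cardiocs_bad_input")
    src <- y$source_id
    y <- y$y
  } else src <- "vector"
  y <- as.numeric(y)
  m <- phi$m
  if (length(y) != m)
    stop_cs("measurement length %d != m = %d", length(y), m, class = "cardiocs_bad_input")
  if (dict_frame_length(dict) != phi$n)
    stop_cs("dictionary frame length %d != sensing N = %d",
            dict_frame_length(dict), phi$n, class = "cardiocs_bad_input")
  n <- n_atoms(dict)
  theta <- phi$phi %*% dict$atoms

  ynorm <- sqrt(sum(y^2))
  if (ynorm == 0) {
    return(structure(list(alpha = numeric(n), dict_id = dict_id(dict),
                          residual_norm = 0, objective = 0, iterations = 0L,
                          status = "optimal", source_id = src),
                     class = "sparse_code"))
  }
  sc <- max(abs(theta))
  ths <- theta / sc
  ys <- y / sc

  if (!relaxed) {
    A <- cbind(ths, -ths)
    sol <- lp_interior_point(A, ys, rep(1, 2L * n), tol = min(tol, 1e-10) * 1e-1,
                             max_iter = max_iter)
    alpha <- sol$z[seq_len(n)] - sol$z[n + seq_len(n)]
  } else {
    eps <- (epsilon %||% (1e-6 * ynorm)) / sc
    bx <- eps / sqrt(m)
    # variables: a+ (n), a- (n), r+ (m), r- (m), w (m slack)
    # Theta(a+ - a-) + r+ - r- = y ;  r+ + r- + w = bx
    A <- rbind(cbind(ths, -ths, diag(m), -diag(m), matrix(0, m, m)),
               cbind(matrix(0, m, 2L * n), diag(m), diag(m), diag(m)))
    cvec <- c(rep(1, 2L * n), rep(0, 3L * m))
    sol <- lp_interior_point(A, c(ys, rep(bx, m)), cvec,
                             tol = min(tol, 1e-10) * 1e-1, max_iter = max_iter)
    alpha <- sol$z[seq_len(n)] - sol$z[n + seq_len(n)]
  }

  alpha <- .bp_polish(alpha, theta, y, tol)
  resid <- sqrt(sum((y - drop(theta %*% alpha))^2))
  feas_tol <- if (relaxed) (epsilon %||% (1e-6 * ynorm)) + tol * max(1, ynorm)
              else tol * max(1, ynorm)
  if (!is.finite(resid) || anyNA(alpha))
    stop_cs("basis pursuit produced non-finite coefficients (status %s)",
            sol$status, class = "cardiocs_solver")
  if (resid > feas_tol)
    stop(structure(class = c("cardiocs_solver", "cardiocs_error", "error", "condition"),
                   list(message = sprintf(
                     "basis pursuit infeasible: residual %.3e exceeds tolerance %.3e (status %s)",
                     resid, feas_tol, sol$status),
                     call = sys.call(-1), residual = resid)))
  structure(list(alpha = alpha, dict_id = dict_id(dict), residual_norm = resid,
                 objective = sum(abs(alpha)), iterations = sol$iterations,
                 status = sol$status, source_id = src),
            class = "sparse_code")
}

# Crossover step: interior-point iterates approach the optimal face from the
# interior, so coefficients that are exactly zero at the optimum linger at
# small nonzero values. Projecting onto the detected support by least squares
# recovers the exact vertex; the polished solution is accepted only when it
# stays feasible and does not increase the l1 objective.
.bp_polish <- function(alpha, theta, y, tol) {
  amax <- max(abs(alpha))
  if (amax == 0) return(alpha)
  obj <- sum(abs(alpha))
  resid0 <- sqrt(sum((y - drop(theta %*% alpha))^2))
  feas <- max(tol * max(1, sqrt(sum(y^2))), resid0)
  for (thr in c(1e-2, 1e-4, 1e-6)) {
    supp <- which(abs(alpha) > thr * amax)
    if (!length(supp) || length(supp) > nrow(theta)) next
    Ts <- theta[, supp, drop = FALSE]
    qrf <- qr(Ts)
    if (qrf$rank < length(supp)) next
    a_s <- qr.coef(qrf, y)
    if (anyNA(a_s)) next
    r <- sqrt(sum((y - drop(Ts %*% a_s))^2))
    if (r <= feas && sum(abs(a_s)) <= obj * (1 + 1e-8) + 1e-12) {
      out <- numeric(length(alpha))
      out[supp] <- a_s
      return(out)
    }
  }
  alpha
}

#' Reconstruct a signal from its sparse code
#'
#' `x_hat = Psi alpha_hat`. When the dictionary was column-normalized at
#' build time the coefficients were solved against the normalized atoms, so
#' the product is already on the original amplitude scale.
#'
#' @param code a `sparse_code` from [basis_pursuit()].
#' @param dict the same dictionary the code was solved against.
#' @return numeric vector of length `dict_frame_length(dict)`.
#' @export
reconstruct <- function(code, dict) {
  stopifnot(inherits(code, "sparse_code"), inherits(dict, "cs_dictionary"))
  if (!identical(code$dict_id, dict_id(dict)))
    stop_cs("sparse code was solved against a different dictionary",
            class = "cardiocs_bad_input")
  drop(dict$atoms %*% code$alpha)
}

#' @export
print.sparse_code <- function(x, ...) {
  nz <- sum(abs(x$alpha) > 1e-6 * max(abs(x$alpha), 1e-300))
  cat(sprintf("<sparse_code> %d coefficients (%d above 1e-6 rel), l1 = %.4g, residual = %.3e, %s in %d it\n",
              length(x$alpha), nz, x$objective, x$residual_norm, x$status, x$iterations))
  invisible(x)
}
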