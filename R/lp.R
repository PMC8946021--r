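# Dense Mehrotra predictor-corrector interior-point solver for the standard
# form linear program
#
#     min c'z   s.t.  A z = b,  z >= 0,
#
# written for the basis-pursuit split (A = [Theta, -Theta], c = 1), where m
# is small (<= 75 here) and n moderate (<= ~3000): each iteration solves the
# m x m normal equations A D A' dl = rhs by Cholesky. Near-degenerate
# optima make D = X S^-1 extremely ill-conditioned, so the scaling is
# capped, steps that inflate the primal residual (which contracts linearly
# in exact arithmetic) are damped, and the best iterate by a residual+gap
# merit is returned.

lp_interior_point <- function(A, b, c, tol = 1e-10, max_iter = 200L) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(c) == n)

  solve_spd <- function(M, rhs) {
    jit <- 0
    for (k in 0:8) {
      R <- tryCatch(chol(M + diag(jit, m)), error = function(e) NULL)
      if (!is.null(R)) return(backsolve(R, forwardsolve(t(R), rhs)))
      jit <- if (jit == 0) 1e-14 * max(diag(M)) else jit * 100
    }
    stop_cs("normal equations not positive definite even with ridge",
            class = "cardiocs_numeric")
  }

  # Mehrotra starting point (primal-feasible up to roundoff)
  AAt <- tcrossprod(A)
  x <- drop(crossprod(A, solve_spd(AAt, b)))
  lam <- drop(solve_spd(AAt, A %*% c))
  s <- c - drop(crossprod(A, lam))
  dx <- max(-1.5 * min(x), 0); ds <- max(-1.5 * min(s), 0)
  x <- x + dx; s <- s + ds
  xs <- sum(x * s)
  if (sum(s) > 0) x <- x + 0.5 * xs / sum(s)
  if (sum(x) > 0) s <- s + 0.5 * xs / sum(x)
  x <- pmax(x, 1e-10); s <- pmax(s, 1e-10)

  bnorm <- 1 + sqrt(sum(b^2)); cnorm <- 1 + sqrt(sum(c^2))
  merit <- function(x, lam, s) {
    rb <- drop(A %*% x) - b
    rc <- drop(crossprod(A, lam)) + s - c
    sqrt(sum(rb^2)) / bnorm + sqrt(sum(rc^2)) / cnorm + sum(x * s) / n
  }
  best <- list(x = x, lam = lam, s = s, merit = merit(x, lam, s))
  stall <- 0L
  status <- "max_iter"
  it <- 0L
  for (it in seq_len(max_iter)) {
    rb <- drop(A %*% x) - b
    rc <- drop(crossprod(A, lam)) + s - c
    rbn <- sqrt(sum(rb^2)); rcn <- sqrt(sum(rc^2))
    mu <- sum(x * s) / n
    if (rbn / bnorm < tol && rcn / cnorm < tol && mu < tol) {
      status <- "optimal"; break
    }
    d <- pmin(x / s, 1e14)
    M <- A %*% (d * t(A))

    # affine (predictor) direction
    dl_aff <- solve_spd(M, -rb - drop(A %*% (d * rc - x)))
    ds_aff <- -rc - drop(crossprod(A, dl_aff))
    dx_aff <- -x - d * ds_aff
    ap <- step_frac(x, dx_aff); ad <- step_frac(s, ds_aff)
    mu_aff <- sum((x + min(1, ap) * dx_aff) * (s + min(1, ad) * ds_aff)) / n
    sigma <- min(1, max((mu_aff / mu)^3, 1e-10))

    # corrector
    rxs <- -x * s + sigma * mu - dx_aff * ds_aff
    dl <- solve_spd(M, -rb - drop(A %*% (d * rc)) - drop(A %*% (rxs / s)))
    ds_ <- -rc - drop(crossprod(A, dl))
    dx_ <- rxs / s - d * ds_

    eta <- 0.99995
    ap <- min(1, eta * step_frac(x, dx_))
    ad <- min(1, eta * step_frac(s, ds_))
    # damp any step whose roundoff inflates the primal residual
    for (h in 1:30) {
      rb_new <- drop(A %*% (x + ap * dx_)) - b
      if (sqrt(sum(rb_new^2)) <= max((1 - 0.5 * ap) * rbn, 0.1 * tol * bnorm)) break
      ap <- ap / 2; ad <- ad / 2
      if (ap < 1e-12) break
    }
    x <- pmax(x + ap * dx_, 1e-300)
    lam <- lam + ad * dl
    s <- pmax(s + ad * ds_, 1e-300)

    mer <- merit(x, lam, s)
    if (mer < best$merit * (1 - 1e-3)) {
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= 15L) { status <- "stalled"; break }
    }
    if (mer < best$merit) best <- list(x = x, lam = lam, s = s, merit = mer)
  }
  rb_f <- drop(A %*% x) - b
  if (merit(x, lam, s) > best$merit) { x <- best$x; lam <- best$lam; s <- best$s }
  list(z = x, lambda = lam, s = s, mu = sum(x * s) / n,
       primal_residual = sqrt(sum((drop(A %*% x) - b)^2)),
       iterations = it, status = status)
}

# largest t in (0, Inf) with v + t*dv >= 0
step_frac <- function(v, dv) {
  neg <- dv < 0
  if (!any(neg)) return(Inf)
  min(-v[neg] / dv[neg])
}
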