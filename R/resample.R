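#' Resample a vector to a new length by cubic-spline interpolation
#'
#' Evaluates a natural cubic spline through `(0, ..., length(x) - 1)` at
#' `n_out` equally spaced points spanning the same interval, so the first and
#' last samples are preserved exactly. This is the single resampling primitive
#' used for pattern normalisation to 301 samples, R-wave centring and its
#' inverse, and beat placement in the synthetic generator.
#'
#' @param x numeric vector, length >= 2.
#' @param n_out target length (>= 2).
#' @return numeric vector of length `n_out`.
#' @export
#' @examples
#' resample_spline(sin(seq(0, pi, length.out = 50)), 301)[c(1, 151, 301)]
resample_spline <- function(x, n_out) {
  n_in <- length(x)
  if (n_in < 2L) stop_cs("resample_spline() needs at least 2 samples, got %d", n_in,
                         class = "cardiocs_bad_input")
  if (n_out < 2L) stop_cs("resample_spline() target length must be >= 2, got %d", n_out,
                          class = "cardiocs_bad_input")
  if (n_out == n_in) return(as.numeric(x))
  f <- stats::splinefun(seq.int(0L, n_in - 1L), x, method = "natural")
  f(seq(0, n_in - 1L, length.out = n_out))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards. Keeps every constructor deterministic
# without clobbering the session RNG.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}
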