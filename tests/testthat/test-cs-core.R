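test_that("compression is the plain matrix-vector product", {
  ones <- projection_matrix <- structure(
    list(phi = matrix(1, 1, 300), kind = "gaussian", seed = 0L,
         dict_ref = NULL, m = 1L, n = 300L), class = "projection_matrix")
  expect_equal(compress(1:300, ones)$y, 45150)
  expect_equal(compress(numeric(300), ones)$y, 0)
  expect_error(compress(1:299, ones), class = "cardiocs_bad_input")
})

test_that("zero measurements code to the zero vector", {
  dict <- fix_gauss_dict()
  phi <- gaussian_matrix(20, 300, seed = 1)
  code <- basis_pursuit(numeric(20), phi, dict)
  expect_equal(code$alpha, numeric(700))
  expect_equal(code$residual_norm, 0)
  expect_equal(reconstruct(code, dict), numeric(300))
})

test_that("1-sparse signals are recovered essentially exactly at m = 20", {
  dict <- fix_gauss_dict()
  phi <- gaussian_matrix(20, 300, seed = 2)
  a0 <- numeric(700); a0[123] <- 1.7
  x <- drop(dict$atoms %*% a0)
  code <- basis_pursuit(compress(x, phi), phi, dict)
  expect_lt(max(abs(code$alpha - a0)), 1e-5)
  expect_lt(prd(x, reconstruct(code, dict)), 0.1)
})

test_that("basis pursuit attains the brute-force minimum l1 norm on tiny instances", {
  set.seed(8)
  for (trial in 1:8) {
    m <- 5L; n <- 10L
    theta <- matrix(rnorm(m * n), m)
    dict <- cs_dictionary(rbind(theta, matrix(0, 1, n)), kind = "patient_raw",
                          normalize = FALSE)   # frame length 6 > m
    phi <- structure(list(phi = cbind(diag(m), numeric(m)), kind = "gaussian",
                          seed = 0L, dict_ref = NULL, m = m, n = 6L),
                     class = "projection_matrix")
    a0 <- numeric(n); a0[sample(n, 2)] <- rnorm(2) + sign(rnorm(2))
    y <- drop(theta %*% a0)
    code <- basis_pursuit(y, phi, dict, tol = 1e-8)
    oracle <- bp_oracle_min_l1(theta, y, kmax = 4)
    expect_lte(code$objective, oracle + 1e-6)
    expect_lt(code$residual_norm, 1e-7)
  }
})

test_that("unit coefficients reproduce dictionary atoms and mismatches error", {
  atoms <- matrix(rnorm(50 * 8), 50)
  dict <- cs_dictionary(atoms, kind = "patient_raw", normalize = FALSE)
  code <- structure(list(alpha = c(0, 0, 1, 0, 0, 0, 0, 0),
                         dict_id = cardiocs:::dict_id(dict),
                         residual_norm = 0, objective = 1),
                    class = "sparse_code")
  expect_equal(reconstruct(code, dict), atoms[, 3])
  other <- cs_dictionary(atoms + 1, kind = "patient_raw", normalize = FALSE)
  expect_error(reconstruct(code, other), class = "cardiocs_bad_input")
})

test_that("measurements are bound to their sensing matrix", {
  dict <- fix_gauss_dict()
  phi1 <- gaussian_matrix(20, 300, seed = 1)
  phi2 <- gaussian_matrix(20, 300, seed = 2)
  y <- compress(dict$atoms[, 1], phi1)
  expect_error(basis_pursuit(y, phi2, dict), class = "cardiocs_bad_input")
})

test_that("reconstruction is deterministic across repeated solves", {
  dict <- fix_gauss_dict()
  phi <- gaussian_matrix(20, 300, seed = 3)
  x <- drop(dict$atoms %*% replace(numeric(700), c(10, 20), c(1, -2)))
  c1 <- basis_pursuit(compress(x, phi), phi, dict)
  c2 <- basis_pursuit(compress(x, phi), phi, dict)
  expect_identical(c1$alpha, c2$alpha)
})

test_that("the relaxed mode tolerates measurement perturbations", {
  dict <- fix_gauss_dict()
  phi <- gaussian_matrix(20, 300, seed = 4)
  x <- drop(dict$atoms %*% replace(numeric(700), 42, 2))
  y <- compress(x, phi)
  y$y <- y$y + 1e-4 * sqrt(sum(y$y^2)) * with_seed(1, rnorm(20)) / sqrt(20)
  eps <- 2e-4 * sqrt(sum(y$y^2))
  code <- basis_pursuit(y, phi, dict, relaxed = TRUE, epsilon = eps)
  expect_lte(code$residual_norm, eps * 1.01)
  xh <- reconstruct(code, dict)
  expect_lt(prd(x, xh), 5)
})

test_that("sparse signals in the dictionary span reconstruct to high fidelity", {
  # k <= 3 atoms at m = 30 sits inside the l1 recovery region (at m = 20 the
  # sparsity k = 3 lies beyond the Donoho-Tanner phase transition for
  # m/N = 1/15, where failures are expected from theory, not from the solver)
  dict <- fix_gauss_dict()
  set.seed(99)
  ok <- 0L
  n_trials <- 40L
  for (t in seq_len(n_trials)) {
    phi <- gaussian_matrix(30, 300, seed = 1000 + t)
    k <- sample(1:3, 1)
    a0 <- replace(numeric(700), sample(700, k), rnorm(k) + sign(rnorm(k)))
    x <- drop(dict$atoms %*% a0)
    code <- tryCatch(basis_pursuit(compress(x, phi), phi, dict),
                     error = function(e) NULL)
    if (!is.null(code) &&
        sqrt(sum((reconstruct(code, dict) - x)^2)) <= 1e-4 * sqrt(sum(x^2)))
      ok <- ok + 1L
  }
  expect_gte(ok / n_trials, 0.95)
})
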