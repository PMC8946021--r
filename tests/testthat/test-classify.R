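# small labelled mega dictionary + matching sensing matrix shared below
fix_small_mega <- function() fixture("small_mega", function() {
  by_class <- fix_patterns_by_class()
  build_mega(by_class, per_class = 60L, seed = 13)
})
fix_small_phi <- function() fixture("small_phi", function()
  gaussian_matrix(20, 301, seed = 14))

test_that("alpha-max picks the largest coefficient's class and flags zero codes", {
  mega <- fix_small_mega()
  mk_code <- function(alpha) structure(
    list(alpha = alpha, dict_id = cardiocs:::dict_id(mega), residual_norm = 0,
         objective = sum(abs(alpha))), class = "sparse_code")
  for (j in c(1L, 100L, 480L)) {
    a <- numeric(480); a[j] <- -2   # sign must not matter
    expect_identical(classify_alpha_max(mk_code(a), mega),
                     as.integer(mega$meta$class_label[j]))
  }
  expect_identical(classify_alpha_max(mk_code(numeric(480)), mega), NA_integer_)
  other <- fix_gauss_dict()
  expect_error(classify_alpha_max(mk_code(numeric(480)), other),
               class = "cardiocs_bad_input")
})

test_that("alpha-max recovers the class of held-out beats end to end", {
  by_class <- fix_patterns_by_class()
  mega <- fix_small_mega()
  phi <- fix_small_phi()
  set.seed(21)
  ok <- 0L; n_trials <- 0L
  for (cl in names(by_class)) {
    pool <- setdiff(seq_along(by_class[[cl]]), mega$consumed$selected[[cl]])
    for (idx in sample(pool, 25)) {
      y <- compress(by_class[[cl]][[idx]], phi)
      hat <- classify_alpha_max(basis_pursuit(y, phi, mega), mega)
      n_trials <- n_trials + 1L
      if (identical(hat, as.integer(cl))) ok <- ok + 1L
    }
  }
  expect_gte(n_trials, 200L)
  expect_gte(ok / n_trials, 0.95)
})

test_that("KNN on compressed atoms maps training vectors to their own labels", {
  mega <- fix_small_mega()
  phi <- fix_small_phi()
  model <- knn_fit(mega, phi, k = 1)
  expect_equal(dim(model$train), c(480L, 20L))
  atoms <- sweep(mega$atoms, 2, mega$norms, "*")
  for (j in c(3L, 77L, 402L)) {
    y <- compress(atoms[, j], phi)
    expect_identical(knn_predict(model, y), as.integer(mega$meta$class_label[j]))
  }
  # phi binding
  other_phi <- gaussian_matrix(20, 301, seed = 99)
  expect_error(knn_predict(model, compress(atoms[, 1], other_phi)),
               class = "cardiocs_bad_input")
  # degenerate k = n -> the tie among balanced classes resolves to class 1
  all_model <- knn_fit(mega, phi, k = n_atoms(mega))
  expect_identical(knn_predict(all_model, compress(atoms[, 402], phi)), 1L)
})

test_that("KNN predictions are invariant to training order and match class::knn", {
  mega <- fix_small_mega()
  phi <- fix_small_phi()
  model <- knn_fit(mega, phi, k = 3)
  perm <- with_seed(5, sample.int(480))
  permuted <- model
  permuted$train <- model$train[perm, , drop = FALSE]
  permuted$labels <- model$labels[perm]
  by_class <- fix_patterns_by_class()
  queries <- lapply(1:8, function(cl) {
    pool <- setdiff(seq_along(by_class[[as.character(cl)]]),
                    mega$consumed$selected[[as.character(cl)]])
    compress(by_class[[as.character(cl)]][[pool[1]]], phi)
  })
  for (q in queries)
    expect_identical(knn_predict(model, q), knn_predict(permuted, q))
  # independent cross-check with class::knn (k = 1: no ties possible)
  m1 <- knn_fit(mega, phi, k = 1)
  ref <- as.integer(as.character(class::knn(
    m1$train, t(vapply(queries, function(q) q$y, numeric(20))),
    factor(m1$labels), k = 1)))
  ours <- vapply(queries, function(q) knn_predict(m1, q), integer(1))
  expect_identical(ours, ref)
})

test_that("KNN separates noise-free template-pure classes perfectly and noise degrades it", {
  tpl <- make_templates(3)
  atoms <- vapply(tpl, function(t) t$waveform, numeric(301))
  train <- do.call(cbind, replicate(5, atoms, simplify = FALSE))
  labels <- rep(1:8, 5)
  mega <- cs_dictionary(train, data.frame(class_label = labels, record_id = NA,
                                          source_index = seq_along(labels)),
                        kind = "mega", normalize = FALSE)
  phi <- gaussian_matrix(20, 301, seed = 31)
  model <- knn_fit(mega, phi, k = 1)
  acc <- function(noise_sd, seed) {
    set.seed(seed)
    hits <- 0L
    for (cl in 1:8) for (r in 1:4) {
      q <- compress(atoms[, cl] + rnorm(301, 0, noise_sd), phi)
      if (knn_predict(model, q) == cl) hits <- hits + 1L
    }
    hits / 32
  }
  expect_equal(acc(0, 1), 1)
  noisy <- mean(vapply(1:10, function(s) acc(0.1, s), numeric(1)))
  clean <- mean(vapply(1:10, function(s) acc(0.01, s), numeric(1)))
  expect_lte(noisy, clean)
})

test_that("the MLP separates separable classes and is seed-reproducible", {
  set.seed(17)
  x <- rbind(matrix(rnorm(200, mean = 0), 100), matrix(rnorm(200, mean = 4), 100))
  labels <- rep(1:2, each = 100)
  m <- mlp_fit(x, labels, seed = 4)
  expect_equal(m$hidden_units, 10L)
  expect_gte(mean(mlp_predict(m, x) == labels), 0.99)
  m2 <- mlp_fit(x, labels, seed = 4)
  expect_identical(mlp_predict(m2, x), mlp_predict(m, x))
  expect_error(mlp_fit(x, rep(1, 200)), class = "cardiocs_bad_input")
})

test_that("the MLP handles the 8-class compressed-atom task", {
  mega <- fix_small_mega()
  phi <- fix_small_phi()
  atoms <- sweep(mega$atoms, 2, mega$norms, "*")
  feats <- t(phi$phi %*% atoms)
  m <- mlp_fit(feats, mega$meta$class_label, seed = 2)
  expect_gte(mean(mlp_predict(m, feats) == mega$meta$class_label), 0.9)
})

test_that("binary collapse and confusion-matrix bookkeeping", {
  expect_identical(collapse_binary(c(1L, 3L, 1L, 8L)), c(1L, 2L, 1L, 2L))
  cm <- confusion_matrix(truth = c(1, 1, 2, 2, 2), predicted = c(1, 2, 2, 2, NA),
                         classes = 1:2)
  expect_equal(unname(rowSums(cm)), c(2L, 3L))
  expect_equal(unname(cm[2, "unclassified"]), 1L)
})
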