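test_that("patient raw dictionaries consume exactly the record prefix", {
  rec <- generate_record(synth_config(820, seed = 31))
  expect_gte(length(rec$samples), 250000)
  d <- build_patient_raw(rec, normalize = FALSE)
  expect_equal(dim(d$atoms), c(300L, 700L))
  expect_equal(d$consumed$prefix_samples, 210000L)
  for (j in c(1L, 350L, 700L))
    expect_equal(d$atoms[, j], rec$samples[(300 * (j - 1) + 1):(300 * j)])
  short <- ecg_record(rnorm(100000), fs = 360)
  expect_error(build_patient_raw(short), "210000", class = "cardiocs_bad_input")
})

test_that("patient pattern dictionaries centre atoms on request and log consumption", {
  rec <- fix_cpcs_record()
  d <- build_patient_patterns(rec, n_beats = 300L, centered = TRUE, normalize = FALSE)
  expect_equal(dim(d$atoms), c(301L, 300L))
  expect_true(all(apply(abs(d$atoms), 2, which.max) == 151L))
  expect_equal(d$consumed$pattern_indices, 1:300)

  d0 <- build_patient_patterns(rec, n_beats = 300L, centered = FALSE, normalize = FALSE)
  expect_identical(d0$meta, d$meta)
  expect_false(isTRUE(all.equal(d0$atoms, d$atoms)))
  expect_error(build_patient_patterns(rec, n_beats = 5000L),
               class = "cardiocs_bad_input")
})

test_that("the mega dictionary is class-balanced and seed-deterministic", {
  by_class <- fix_patterns_by_class()
  expect_setequal(names(by_class), as.character(1:8))
  n_min <- min(vapply(by_class, length, integer(1)))
  per <- min(50L, n_min)
  mega <- build_mega(by_class, per_class = per, seed = 5)
  expect_equal(n_atoms(mega), 8L * per)
  expect_true(all(table(mega$meta$class_label) == per))
  mega2 <- build_mega(by_class, per_class = per, seed = 5)
  expect_identical(mega$atoms, mega2$atoms)
  expect_identical(mega$consumed$selected, mega2$consumed$selected)

  tiny <- build_mega(by_class, per_class = 1L, seed = 1)
  expect_equal(n_atoms(tiny), 8L)
  expect_equal(sort(tiny$meta$class_label), 1:8)

  starved <- by_class
  starved[["3"]] <- starved[["3"]][1:2]
  expect_error(build_mega(starved, per_class = 10L), "class 3",
               class = "cardiocs_bad_input")
})

test_that("class dictionaries are single-class and disjoint from held-out patterns", {
  by_class <- fix_patterns_by_class()
  n_min <- min(vapply(by_class, length, integer(1)))
  dicts <- build_class_dictionaries(by_class, n_atoms = min(60L, n_min), seed = 2)
  expect_length(dicts, 8L)
  for (cl in names(dicts)) {
    d <- dicts[[cl]]
    expect_true(all(d$meta$class_label == as.integer(cl)))
    held_out <- setdiff(seq_along(by_class[[cl]]), d$consumed$selected)
    expect_length(intersect(d$consumed$selected, held_out), 0L)
    expect_gt(length(held_out), 0L)
  }
})

test_that("atom normalization gives unit columns and leaves reconstructions unchanged", {
  rec <- fix_cpcs_record()
  dn <- build_patient_patterns(rec, n_beats = 310L, normalize = TRUE)
  expect_equal(sqrt(colSums(dn$atoms^2)), rep(1, 310), tolerance = 1e-12)

  du <- build_patient_patterns(rec, n_beats = 310L, normalize = FALSE)
  phi <- gaussian_matrix(20, 301, seed = 9)
  x <- du$atoms[, 305] * 1.4          # a held-in atom as test signal
  xh_n <- reconstruct(basis_pursuit(compress(x, phi), phi, dn), dn)
  xh_u <- reconstruct(basis_pursuit(compress(x, phi), phi, du), du)
  expect_equal(xh_n, xh_u, tolerance = 1e-5)
})

test_that("flat atoms are rejected", {
  bad <- cbind(matrix(rnorm(20), 10), rep(0, 10))
  expect_error(cs_dictionary(bad), class = "cardiocs_bad_input")
})
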