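test_that("PSCCS rejects records shorter than the dictionary prefix before solving", {
  short <- ecg_record(rnorm(50000), fs = 360)
  expect_error(run_psccs(short), class = "cardiocs_bad_input")
})

test_that("PSCCS reconstructs held-out frames and degrades with compression", {
  rec <- fix_patient_record()
  r4 <- run_psccs(rec, cr_label = 4, matrix_kind = "gaussian",
                  n_test_frames = 6, seed = 1)
  r15 <- run_psccs(rec, cr_label = 15, matrix_kind = "gaussian",
                   n_test_frames = 6, seed = 1)
  expect_s3_class(r4$report, "distortion_report")
  expect_equal(nrow(r4$report), 6L)
  expect_equal(attr(r4$report, "cr"), 4)
  expect_equal(attr(r15$report, "cr"), 15)
  expect_lt(attr(r4$summary, "avg_prd"), attr(r15$summary, "avg_prd"))
  expect_length(r4$reconstructed, 6L * 300L)
})

test_that("a test frame equal to a dictionary atom reconstructs near-perfectly", {
  rec <- fix_patient_record()
  dict <- build_patient_raw(rec)
  phi <- gaussian_matrix(20, 300, seed = 5)
  x <- sweep(dict$atoms, 2, dict$norms, "*")[, 123]   # original-amplitude atom
  code <- basis_pursuit(compress(x, phi), phi, dict)
  expect_lte(prd(x, reconstruct(code, dict)), 0.1)
})

test_that("CPCS configuration errors surface before any solve", {
  rec <- fix_cpcs_record()
  expect_error(run_cpcs(rec, branch = "specific", classifier = NULL),
               class = "cardiocs_bad_input")
})

test_that("CPCS mega branch reports distortion, classes and dictionary exclusion", {
  rec <- fix_cpcs_record()
  res <- run_cpcs(rec, branch = "mega", center = TRUE, per_class = 60L,
                  n_test_per_class = 3L, seed = 7)
  expect_equal(nrow(res$report), 24L)
  expect_equal(attr(res$report, "cr"), 301 / 20)
  expect_equal(nrow(res$classes), 24L)
  expect_equal(unname(rowSums(res$confusion)), rep(3L, 8L))
  expect_gte(res$accuracy, 0.7)
  # determinism of a full run
  res2 <- run_cpcs(rec, branch = "mega", center = TRUE, per_class = 60L,
                   n_test_per_class = 3L, seed = 7)
  expect_identical(res$report$prd, res2$report$prd)
  expect_identical(res$classes, res2$classes)
})

test_that("CPCS specific branch works with each classifier", {
  rec <- fix_cpcs_record()
  for (clf in c("oracle", "knn")) {
    res <- run_cpcs(rec, branch = "specific", classifier = clf, center = TRUE,
                    per_class = 40L, class_dict_atoms = 40L,
                    n_test_per_class = 2L, seed = 3)
    expect_equal(nrow(res$report), 16L)
    expect_true(all(res$report$prd >= 0))
    if (clf == "oracle") expect_equal(res$accuracy, 1)
  }
})

test_that("CPCS patient branch holds out the beats consumed by its dictionary", {
  rec <- fix_cpcs_record()
  res <- run_cpcs(rec, branch = "patient", center = TRUE,
                  patient_dict_beats = 400L, n_test_per_class = 10L, seed = 2)
  expect_equal(nrow(res$report), 10L)
  expect_equal(n_atoms(res$dict), 400L)
})

test_that("the 15:1 summary grid covers all matrix/setting cells", {
  rec <- generate_record(synth_config(700, seed = 55))
  tab <- suppressWarnings(
    run_table9(rec, seeds = 1L, classifier = "oracle",
               n_atoms = 400L, n_test_frames = 2L, per_class = 40L,
               class_dict_atoms = 30L, patient_dict_beats = 310L,
               n_test_per_class = 2L))
  expect_equal(nrow(tab), 18L)
  expect_setequal(unique(tab$setting),
                  c("psccs_raw", "mega", "mega_centered", "specific",
                    "specific_centered", "patient_centered"))
  expect_setequal(unique(tab$matrix), c("optimized", "bernoulli", "gaussian"))
  expect_true(all(is.finite(tab$avg_prd)))
  expect_true(all(is.finite(tab$qs)))
})
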