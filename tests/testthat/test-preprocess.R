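test_that("detector returns nothing on flat signal and everything on clean beats", {
  flat <- ecg_record(rep(0, 2000), fs = 360)
  expect_identical(detect_r_peaks(flat), integer(0))
  expect_error(detect_r_peaks(ecg_record(rep(0, 100), fs = 360)),
               class = "cardiocs_bad_input")

  rec <- fix_clean_record()
  pk <- detect_r_peaks(rec)
  truth <- rec$annotations$r_index
  expect_equal(length(pk), length(truth))
  expect_lte(max(abs(pk - truth)), 2)
})

test_that("detector meets sensitivity and precision targets on noisy beats", {
  rec <- fix_noisy_record()
  s <- score_detection(detect_r_peaks(rec), rec$annotations$r_index, rec$fs)
  expect_gte(s$sensitivity, 0.99)
  expect_gte(s$ppv, 0.99)
})

test_that("detector is deterministic and honours annotation passthrough", {
  rec <- fix_noisy_record()
  expect_identical(detect_r_peaks(rec), detect_r_peaks(rec))
  expect_identical(detect_r_peaks(rec, use_annotations = TRUE),
                   rec$annotations$r_index)
})

test_that("framing tiles the signal prefix without overlap or gap", {
  rec <- ecg_record(seq_len(900) / 900, fs = 360)
  f <- frame_signal(rec)
  expect_equal(dim(f), c(300L, 3L))
  expect_equal(attr(f, "start_index"), c(0L, 300L, 600L))
  expect_equal(as.numeric(f), rec$samples[1:900])

  rec2 <- ecg_record(seq_len(899), fs = 360)
  expect_message(f2 <- frame_signal(rec2), "dropped 299")
  expect_equal(ncol(f2), 2L)
  expect_error(frame_signal(ecg_record(1:100 / 100, fs = 360)),
               class = "cardiocs_bad_input")
})

test_that("pattern bounds follow RR midpoints", {
  x <- sin(seq(0, 40 * pi, length.out = 1500))
  rec <- ecg_record(x, fs = 360)
  pats <- segment_patterns(rec, r_peaks = c(300L, 700L, 1000L))
  expect_length(pats, 1L)
  expect_equal(pats[[1]]$reversal$orig_start, 500L)
  expect_equal(pats[[1]]$reversal$orig_end, 850L)
  expect_length(pats[[1]]$x, 301L)
  expect_warning(p0 <- segment_patterns(rec, r_peaks = c(300L, 700L)), "fewer than 3")
  expect_length(p0, 0L)
})

test_that("periodic records give centred patterns spanning one RR interval", {
  cfg <- synth_config(12, mean_rr = 1.0, rr_jitter_sd = 0, noise_sd = 0,
                      baseline_wander_amplitude = 0, seed = 6)
  rec <- generate_record(cfg)
  pats <- segment_patterns(rec)
  for (p in pats) {
    expect_equal(p$r_index, 150L)
    expect_equal(p$reversal$orig_end - p$reversal$orig_start, 360L)
  }
  # spans tile the record between the first and last midpoints
  starts <- vapply(pats, function(p) p$reversal$orig_start, integer(1))
  ends <- vapply(pats, function(p) p$reversal$orig_end, integer(1))
  expect_equal(starts[-1], ends[-length(ends)])
})

test_that("patterns resample back to their raw span within tolerance", {
  rec <- fix_clean_record()
  pats <- segment_patterns(rec)
  peak <- max(abs(rec$samples))
  for (p in pats[seq(1, length(pats), by = 10)]) {
    raw <- rec$samples[(p$reversal$orig_start:p$reversal$orig_end) + 1]
    expect_lt(max(abs(pattern_to_raw(p) - raw)), 0.01 * peak)
  }
})

test_that("centering is exact at the R knot and reversible", {
  rec <- fix_clean_record()
  pats <- segment_patterns(rec)
  p <- pats[[which(vapply(pats, function(q) q$r_index, integer(1)) != 150L)[1]]]
  pc <- center_pattern(p)
  expect_equal(pc$r_index, 150L)
  expect_equal(pc$x[151], p$x[p$r_index + 1])
  expect_equal(which.max(abs(pc$x)), 151L)
  expect_equal(pc$reversal$left_len, p$r_index + 1L)
  expect_equal(pc$reversal$right_len, 301L - p$r_index)

  pu <- uncenter_pattern(pc)
  expect_equal(pu$r_index, p$r_index)
  expect_lt(max(abs(pu$x - p$x)), 0.01 * max(abs(p$x)))

  # identity stretch when already centred
  q <- pats[[which(vapply(pats, function(q) q$r_index, integer(1)) == 150L)[1]]]
  expect_equal(center_pattern(q)$x, q$x, tolerance = 1e-12)
})

test_that("degenerate or meta-stripped centering requests error", {
  p <- cardiac_pattern(sin(seq(0, pi, length.out = 301)), r_index = 0L)
  expect_error(center_pattern(p), class = "cardiocs_bad_input")
  ok <- cardiac_pattern(c(seq(0, 1, length.out = 101), seq(1, 0, length.out = 200)),
                        r_index = 100L)
  pc <- center_pattern(ok)
  expect_error(center_pattern(pc), class = "cardiocs_bad_input")
  pc$reversal$left_len <- NULL
  expect_error(uncenter_pattern(pc), class = "cardiocs_bad_input")
  expect_error(uncenter_pattern(ok), class = "cardiocs_bad_input")
})
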