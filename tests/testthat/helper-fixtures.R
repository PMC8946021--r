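# Shared fixtures, built once per test run and memoised (several files reuse
# the same synthetic records and dictionaries).

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# clean multi-class record: 250 beats, no noise/wander
fix_clean_record <- function() fixture("clean_record", function()
  generate_record(synth_config(250, noise_sd = 0, baseline_wander_amplitude = 0,
                               seed = 101)))

# default-noise multi-class record with 1000 beats (CPCS material)
fix_cpcs_record <- function() fixture("cpcs_record", function()
  generate_record(synth_config(1000, seed = 202)))

# patient-like record (one dominant morphology) long enough for a 700-atom
# raw dictionary plus test frames
fix_patient_record <- function() fixture("patient_record", function()
  generate_record(synth_config(900, class_sequence = c(0.90, 0.02, 0.02, 0.02,
                                                       0.01, 0.01, 0.01, 0.01),
                               seed = 303)))

# noisy 500-beat record for detector scoring (noise 5% of ~1 mV peak)
fix_noisy_record <- function() fixture("noisy_record", function()
  generate_record(synth_config(500, noise_sd = 0.05, seed = 404)))

# Gaussian test dictionary 300 x 700 (unit-norm columns)
fix_gauss_dict <- function() fixture("gauss_dict", function()
  with_seed(7, cs_dictionary(matrix(stats::rnorm(300 * 700), 300),
                             kind = "patient_raw")))

# labelled patterns of the CPCS record, grouped by class
fix_patterns_by_class <- function() fixture("patterns_by_class", function()
  split_patterns_by_class(segment_patterns(fix_cpcs_record())))

# Independent l1 oracle: enumerate all supports of size <= kmax, keep the
# exactly feasible least-squares solutions, and return the smallest l1 norm
# found (Inf when none is feasible). Brute force by construction; used to
# check basis-pursuit optimality on tiny instances.
bp_oracle_min_l1 <- function(theta, y, kmax, feas_tol = 1e-8) {
  n <- ncol(theta)
  best <- Inf
  for (k in seq_len(kmax)) {
    for (supp in utils::combn(n, k, simplify = FALSE)) {
      Ts <- theta[, supp, drop = FALSE]
      qrf <- qr(Ts)
      if (qrf$rank < k) next
      a <- qr.coef(qrf, y)
      if (max(abs(drop(Ts %*% a) - y)) < feas_tol)
        best <- min(best, sum(abs(a)))
    }
  }
  best
}

# Minimal MIT-format annotation writer for fixtures (built at test time; the
# package deliberately does not write annotation files). Supports plain
# words and the SKIP escape for intervals > 1023.
write_test_atr <- function(path, samples, codes) {
  con <- file(path, "wb")
  on.exit(close(con))
  emit <- function(b1, b2) writeBin(as.raw(c(b1, b2)), con)
  prev <- 0L
  for (i in seq_along(samples)) {
    iv <- samples[i] - prev
    prev <- samples[i]
    if (iv > 1023L) {
      emit(0L, bitwShiftL(59L, 2))                       # SKIP, interval 0
      hi <- iv %/% 65536L; lo <- iv %% 65536L
      emit(hi %% 256L, hi %/% 256L)
      emit(lo %% 256L, lo %/% 256L)
      iv <- 0L
    }
    emit(iv %% 256L, bitwOr(bitwShiftL(codes[i], 2), iv %/% 256L))
  }
  emit(0L, 0L)                                            # EOF
  invisible(path)
}
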