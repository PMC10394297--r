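test_that("cohort generation is deterministic under a fixed seed", {
  spec <- synthetic_cohort_spec(n_patients = 2, n_channels = 3,
                                seconds_per_class_per_patient = 4, seed = 5)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1, c2)
  c3 <- generate_cohort(synthetic_cohort_spec(n_patients = 2, n_channels = 3,
                                              seconds_per_class_per_patient = 4,
                                              seed = 6))
  expect_false(identical(c1[[1]]$signal$samples, c3[[1]]$signal$samples))
})

test_that("generated recordings are finite and fully annotated", {
  spec <- synthetic_cohort_spec(n_patients = 3, n_channels = 4,
                                seconds_per_class_per_patient = 5, seed = 2)
  cohort <- generate_cohort(spec)
  expect_length(cohort, 3L)
  for (p in cohort) {
    expect_true(all(is.finite(p$signal$samples)))
    expect_equal(dim(p$signal$samples), c(4L, 2L * 5L * 250L))
    # annotation tiles the recording with no gaps
    expect_equal(p$annotation$start_s, c(0, 5))
    expect_equal(p$annotation$stop_s, c(5, 10))
    expect_equal(p$annotation$label, c("bckg", "seiz"))
  }
  expect_error(synthetic_cohort_spec(class_band_hz = c(100, 200)),
               class = "seizdg_validation_error")
})

test_that("zero class amplitude makes classes indistinguishable", {
  spec <- synthetic_cohort_spec(n_patients = 3, n_channels = 3,
                                seconds_per_class_per_patient = 45,
                                class_amplitude = 0, seed = 13)
  batches <- cohort_to_batches(generate_cohort(spec))
  bp <- unlist(lapply(batches, seizdg:::segment_bandpower, band_hz = c(4, 8)))
  y <- unlist(lapply(batches, function(b) b$y))
  expect_gte(length(y), 500)
  # best single-threshold classifier on class-band power ~ chance
  ts <- stats::quantile(bp, seq(0.05, 0.95, 0.05))
  best <- max(vapply(ts, function(t) max(mean((bp > t) == y),
                                         mean((bp <= t) == y)), 0))
  expect_lt(best, 0.55 + 0.05)
})

test_that("a strong class amplitude is detectable by band power alone", {
  # frequency jitter is held at zero so the signature stays inside the
  # measured class band; the other patient confounds remain active
  spec <- synthetic_cohort_spec(n_patients = 2, n_channels = 3,
                                seconds_per_class_per_patient = 30,
                                class_amplitude = 5,
                                patient_freq_jitter_hz = 0, seed = 13)
  batches <- cohort_to_batches(generate_cohort(spec))
  for (b in batches) {
    bp <- seizdg:::segment_bandpower(b, c(4, 8))
    t <- stats::quantile(bp, mean(b$y == 0))
    acc <- max(mean((bp > t) == b$y), mean((bp <= t) == b$y))
    expect_gte(acc, 0.95)
  }
})

test_that("cohort batching yields the documented segment counts", {
  spec <- synthetic_cohort_spec(n_patients = 2, n_channels = 2,
                                seconds_per_class_per_patient = 250, seed = 3)
  batches <- cohort_to_batches(generate_cohort(spec))
  expect_length(batches, 2L)
  for (b in batches) {
    expect_equal(b$n, 999L)                        # 500 s at 50% overlap
    expect_equal(mean(b$y), 0.5, tolerance = 0.01) # balanced classes
    expect_true(all(b$x >= 0 & b$x <= 1))
  }
  expect_equal(unique(batches[[1]]$patient_label), 1L)
  expect_equal(unique(batches[[2]]$patient_label), 2L)
  expect_error(cohort_to_batches(list()), class = "seizdg_validation_error")
  expect_error(
    cohort_to_batches(generate_cohort(
      synthetic_cohort_spec(n_patients = 1, n_channels = 1,
                            seconds_per_class_per_patient = 0.4, seed = 1)),
      window_len = 500),
    class = "seizdg_empty_batch_error")
})

test_that("patient confounds are decodable and induce a generalization gap", {
  spec <- synthetic_cohort_spec(n_patients = 4, n_channels = 3,
                                seconds_per_class_per_patient = 20,
                                class_amplitude = 2.5, patient_gain_sd = 0.8,
                                patient_freq_jitter_hz = 2.5,
                                patient_slope_jitter = 0.5, seed = 11)
  batches <- cohort_to_batches(generate_cohort(spec))
  # narrow-band (1 Hz bins) log power per segment: flexible enough to fit a
  # patient-specific seizure frequency, like an overparameterized network
  feats <- function(b) {
    sapply(2:11, function(f0) seizdg:::segment_bandpower(b, c(f0, f0 + 1)))
  }
  Fa <- do.call(rbind, lapply(batches, feats))
  d <- unlist(lapply(batches, function(b) b$patient_label))
  y <- unlist(lapply(batches, function(b) b$y))
  # the confound exists: patient identity is decodable above chance
  expect_gt(linear_probe_accuracy(Fa, d, seed = 1), 1 / 4 + 0.1)
  # and it hurts transfer: a probe trained on the other patients is worse
  # on patient 4 than a probe trained within patient 4
  tr <- seq_len(sum(vapply(batches[1:3], function(b) b$n, 0L)))
  te <- setdiff(seq_along(y), tr)
  fit <- suppressWarnings(stats::glm.fit(cbind(1, Fa[tr, ]), y[tr],
                                         family = stats::binomial()))
  cross <- mean((Fa[te, ] %*% fit$coefficients[-1] +
                   fit$coefficients[1] > 0) == y[te])
  within <- linear_probe_accuracy(Fa[te, ], y[te], seed = 2)
  expect_gt(within - cross, 0.02)
})

test_that("EDF round trip through the real reader works for synthetic data", {
  spec <- synthetic_cohort_spec(n_patients = 1, n_channels = 2,
                                seconds_per_class_per_patient = 2, seed = 9)
  cohort <- generate_cohort(spec)
  path <- tempfile(fileext = ".edf")
  write_edf_recording(cohort[[1]]$signal, path)
  back <- read_edf_recording(path, patient_id = cohort[[1]]$signal$patient_id)
  rng <- apply(cohort[[1]]$signal$samples, 1, function(v) diff(range(v)))
  for (ch in 1:2) {
    expect_lt(max(abs(back$samples[ch, ] - cohort[[1]]$signal$samples[ch, ])),
              2 * rng[ch] / 65535)
  }
  unlink(path)
})
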