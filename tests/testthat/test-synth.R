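test_that("default cohort has the expected shape and class balance", {
  cohort <- generate_cohort(synth_config(seed = 42))
  expect_length(cohort$recordings, 55L)
  expect_identical(sum(cohort$manifest$label == 0L), 29L)
  expect_identical(sum(cohort$manifest$label == 1L), 26L)
  r1 <- cohort$recordings[[1L]]
  expect_identical(dim(r1$signal), c(3L, 22500L))
  expect_identical(r1$channel_names, c("Fp1", "Fpz", "Fp2"))
  expect_equal(recording_duration(r1), 90)
})

test_that("generation is bit-identical under a fixed seed and per subject", {
  cfg <- synth_config(duration = 10, sampling_rate = 125, seed = 7L,
                      n_healthy = 4L, n_depressed = 4L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)

  # subject-level child seeds: shrinking the cohort keeps earlier subjects
  small <- generate_cohort(synth_config(duration = 10, sampling_rate = 125,
                                        seed = 7L, n_healthy = 2L,
                                        n_depressed = 0L))
  expect_identical(small$recordings[[1L]], a$recordings[[1L]])
  expect_identical(small$recordings[[2L]], a$recordings[[2L]])
})

test_that("zero effects and artifacts make the groups exchangeable", {
  cfg <- synth_config(duration = 20, sampling_rate = 125,
                      n_healthy = 14L, n_depressed = 14L,
                      amp_effect = 0, roughness_effect = 0, mean_effect = 0,
                      subject_sd = 0, blink_rate = 0, powerline_amp = 0,
                      seed = 11L)
  cohort <- generate_cohort(cfg)
  segs <- unlist(lapply(cohort$recordings, segment_recording,
                        cfg = preprocess_config(chunk_seconds = 20)),
                 recursive = FALSE)
  fm <- extract_features(segs)
  y <- fm$instances$label
  # population means equal by construction: standardized group differences
  # stay small across all 36 columns
  z <- apply(fm$values, 2L, function(v) {
    (mean(v[y == 1L]) - mean(v[y == 0L])) /
      sqrt(stats::var(v[y == 1L]) / sum(y == 1L) +
             stats::var(v[y == 0L]) / sum(y == 0L))
  })
  expect_lt(max(abs(z)), 4.5)
  expect_lt(mean(abs(z) > 2), 0.25)
})

test_that("margin = 0 separable cohort reduces to zero-effect generation", {
  cfg <- synth_config(duration = 10, sampling_rate = 125, seed = 5L,
                      n_healthy = 3L, n_depressed = 3L)
  sep <- generate_separable_cohort(cfg, margin = 0)
  cfg0 <- cfg
  cfg0$amp_effect <- 0
  cfg0$roughness_effect <- 0
  cfg0$mean_effect <- 0
  expect_identical(sep, generate_cohort(cfg0))
})

test_that("margin = 3 separates the four majority features by >= 3 sd", {
  fm <- separable_fm()
  y <- fm$instances$label
  for (f in c("max_amp", "min_amp", "mad1", "mad2")) {
    for (e in c("Fp1", "Fpz", "Fp2")) {
      v <- fm$values[, paste0(e, "_", f)]
      sep <- abs(mean(v[y == 1L]) - mean(v[y == 0L])) /
        sqrt((stats::var(v[y == 1L]) + stats::var(v[y == 0L])) / 2)
      expect_gt(sep, 3)
    }
  }
})

test_that("a mean-only group effect moves mean columns but not entropy", {
  base <- synth_config(duration = 20, sampling_rate = 125,
                       n_healthy = 14L, n_depressed = 14L,
                       amp_effect = 0, roughness_effect = 0,
                       mean_effect = 15, subject_sd = 0,
                       blink_rate = 0, powerline_amp = 0, seed = 13L)
  cohort <- generate_cohort(base)
  # raw windows (no average reference, which would remove a common offset)
  segs <- unlist(lapply(cohort$recordings, segment_recording,
                        cfg = preprocess_config(chunk_seconds = 20)),
                 recursive = FALSE)
  fm <- extract_features(segs)
  y <- fm$instances$label
  dmean <- mean(fm$values[y == 1L, "Fp1_mean"]) -
    mean(fm$values[y == 0L, "Fp1_mean"])
  expect_equal(dmean, 15, tolerance = 0.15)
  tt <- feature_ttests(fm, c("Fp1_entropy", "Fpz_entropy", "Fp2_entropy"))
  expect_true(all(abs(tt$t) < 4))
})

test_that("cohorts write to disk with manifest and resolved config", {
  cfg <- synth_config(duration = 2, sampling_rate = 125, seed = 3L,
                      n_healthy = 2L, n_depressed = 1L)
  cohort <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir, format = "csv", config = cfg)
  expect_setequal(list.files(dir),
                  c("subj001.csv", "subj002.csv", "subj003.csv",
                    "manifest.csv", "synth_config.json"))
  m <- read_manifest(file.path(dir, "manifest.csv"))
  expect_identical(m$label, cohort$manifest$label)
  back <- read_matrix(file.path(dir, "subj001.csv"), 125, m)
  expect_equal(back$signal, cohort$recordings[[1L]]$signal,
               tolerance = 1e-8, ignore_attr = TRUE)
})
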