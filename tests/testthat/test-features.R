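test_that("hand-checked values of the temporal statistics are exact", {
  expect_identical(max_amp(c(-3, 0, 7)), 7)
  expect_identical(min_amp(c(-3, 0, 7)), -3)
  expect_identical(p2p_value(c(-3, 0, 7)), 10)
  expect_equal(mean_amp(1:3), 2)
  expect_equal(std_amp(1:3), sqrt(2 / 3))
  expect_equal(kurtosis(c(-1, 1, -1, 1)), 1)
  expect_equal(skewness(c(-1, 0, 1)), 0)
  expect_equal(mad1(c(1, 2, 4, 8)), 7 / 3)
  expect_equal(mad2(c(1, 2, 3, 4)), 0)           # second difference of a line
  expect_equal(energy(1:3), 14 / 3)
  expect_equal(shannon_entropy(rep(5, 10)), 0)   # single occupied bin
  # exactly uniform occupancy of B bins -> log2(B)
  expect_equal(shannon_entropy(c(0.5, 1.5, 2.5, 3.5), bins = 4L), 2)
  # signed peak-to-peak time: max at sample 101, min at sample 51, 250 Hz
  s <- numeric(200); s[101] <- 5; s[51] <- -5
  expect_equal(p2p_time(s, 250), 0.2)
  expect_equal(p2p_time(-s, 250), -0.2)
})

test_that("every statistic matches its brute-force oracle on random windows", {
  set.seed(100)
  for (i in 1:300) {
    n <- sample(5:200, 1L)
    fs <- sample(c(100, 250, 500), 1L)
    s <- rnorm(n) * 10^runif(1, -2, 2) + runif(1, -50, 50)
    expect_equal(max_amp(s), oracle_max(s), tolerance = 1e-9)
    expect_equal(min_amp(s), oracle_min(s), tolerance = 1e-9)
    expect_equal(mean_amp(s), oracle_mean(s), tolerance = 1e-9)
    expect_equal(std_amp(s), oracle_std(s), tolerance = 1e-9)
    expect_equal(kurtosis(s), oracle_kurtosis(s), tolerance = 1e-9)
    expect_equal(skewness(s), oracle_skewness(s), tolerance = 1e-9)
    expect_equal(p2p_value(s), oracle_p2p(s), tolerance = 1e-9)
    expect_equal(p2p_time(s, fs), oracle_p2p_time(s, fs), tolerance = 1e-9)
    expect_equal(mad1(s), oracle_mad1(s), tolerance = 1e-9)
    expect_equal(mad2(s), oracle_mad2(s), tolerance = 1e-9)
    expect_equal(energy(s), oracle_energy(s), tolerance = 1e-9)
    expect_equal(shannon_entropy(s), oracle_entropy(s), tolerance = 1e-9)
  }
})

test_that("peak ties resolve to the first occurrence in time", {
  s <- c(0, 3, -2, 3, -2, 1)      # max at 2 and 4, min at 3 and 5
  expect_equal(p2p_time(s, 1), oracle_p2p_time(s, 1))
  expect_equal(p2p_time(s, 1), -1)  # first max (2) minus first min (3)
})

test_that("shift and scale behaviour of the statistics is as expected", {
  set.seed(7)
  s <- rnorm(400) * 12
  c_shift <- 8.5
  expect_equal(max_amp(s + c_shift), max_amp(s) + c_shift)
  expect_equal(min_amp(s + c_shift), min_amp(s) + c_shift)
  expect_equal(mean_amp(s + c_shift), mean_amp(s) + c_shift)
  for (f in list(std_amp, kurtosis, skewness, p2p_value, mad1, mad2)) {
    expect_equal(f(s + c_shift), f(s), tolerance = 1e-9)
  }
  expect_equal(p2p_time(s + c_shift, 100), p2p_time(s, 100))

  k <- 2.7
  expect_equal(std_amp(k * s), k * std_amp(s))
  expect_equal(p2p_value(k * s), k * p2p_value(s))
  expect_equal(mad1(k * s), k * mad1(s))
  expect_equal(energy(k * s), k^2 * energy(s), tolerance = 1e-9)
  expect_equal(kurtosis(k * s), kurtosis(s), tolerance = 1e-9)
  expect_equal(skewness(k * s), skewness(s), tolerance = 1e-9)
  expect_equal(skewness(-s), -skewness(s), tolerance = 1e-9)
})

test_that("kurtosis of a large Gaussian sample approaches 3", {
  set.seed(12)
  expect_equal(kurtosis(rnorm(2e5)), 3, tolerance = 0.05)
})

test_that("zero-variance windows raise undefined-feature errors", {
  expect_error(kurtosis(rep(2, 10)), "zero-variance")
  expect_error(skewness(rep(2, 10)), "zero-variance")
  expect_equal(std_amp(rep(2, 10)), 0)
  expect_equal(mad1(rep(2, 10)), 0)
  expect_equal(mad2(rep(2, 10)), 0)

  # extract surfaces the subject and window of the offending segment
  rec <- eeg_recording("flatline", matrix(1, nrow = 2, ncol = 100), 10,
                       c("c1", "c2"), label = 0L)
  segs <- segment_recording(rec, preprocess_config(chunk_seconds = 10,
                                                   window_seconds = 10))
  expect_error(extract_features(segs), "flatline.*window 0")
})

test_that("extraction is deterministic and shape-correct", {
  fm <- separable_fm()
  expect_identical(dim(fm), c(220L, 36L))
  expect_false(anyNA(fm$values))
  expect_identical(colnames(fm$values),
                   feature_column_names(c("Fp1", "Fpz", "Fp2")))

  # single segment, single channel -> 1 x 12
  rec <- make_test_recording(n_ch = 1L, n_s = 100L, fs = 10, seed = 8L)
  seg <- segment_recording(rec, preprocess_config(chunk_seconds = 10,
                                                  window_seconds = 10))
  one <- extract_features(seg)
  expect_identical(dim(one), c(1L, 12L))

  # permuting segment order permutes rows identically
  cohort <- generate_cohort(synth_config(duration = 10, sampling_rate = 125,
                                         n_healthy = 3L, n_depressed = 3L,
                                         seed = 2L))
  segs <- unlist(lapply(cohort$recordings, segment_recording,
                        cfg = preprocess_config(chunk_seconds = 10)),
                 recursive = FALSE)
  fm1 <- extract_features(segs)
  perm <- c(4L, 2L, 6L, 1L, 3L, 5L)
  fm2 <- extract_features(segs[perm])
  expect_equal(fm2$values, fm1$values[perm, ], ignore_attr = TRUE)
  expect_identical(fm2$instances$subject_id, fm1$instances$subject_id[perm])
})
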