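# Independent brute-force oracles for the twelve temporal statistics,
# written deliberately with naive loops / different primitives than the
# package implementations.

oracle_max <- function(s) sort(s)[length(s)]
oracle_min <- function(s) sort(s)[1L]
oracle_mean <- function(s) {
  acc <- 0
  for (v in s) acc <- acc + v
  acc / length(s)
}
oracle_std <- function(s) {
  m <- oracle_mean(s)
  acc <- 0
  for (v in s) acc <- acc + (v - m)^2
  sqrt(acc / length(s))
}
oracle_kurtosis <- function(s) {
  m <- oracle_mean(s)
  m2 <- oracle_mean((s - m)^2)
  m4 <- oracle_mean((s - m)^4)
  m4 / m2^2
}
oracle_skewness <- function(s) {
  m <- oracle_mean(s)
  oracle_mean(((s - m) / oracle_std(s))^3)
}
oracle_p2p <- function(s) oracle_max(s) - oracle_min(s)
oracle_p2p_time <- function(s, fs) {
  i_max <- NA; i_min <- NA
  for (i in seq_along(s)) {            # scan order = first occurrence
    if (is.na(i_max) || s[i] > s[i_max]) i_max <- i
    if (is.na(i_min) || s[i] < s[i_min]) i_min <- i
  }
  (i_max - i_min) / fs
}
oracle_mad1 <- function(s) {
  acc <- 0
  for (i in seq_len(length(s) - 1L)) acc <- acc + abs(s[i + 1L] - s[i])
  acc / (length(s) - 1L)
}
oracle_mad2 <- function(s) {
  acc <- 0
  for (i in 3:length(s)) acc <- acc + abs(s[i] - 2 * s[i - 1L] + s[i - 2L])
  acc / (length(s) - 2L)
}
oracle_energy <- function(s) oracle_mean(s^2)
oracle_entropy <- function(s, bins = 16L) {
  lo <- oracle_min(s); hi <- oracle_max(s)
  if (hi == lo) return(0)
  counts <- integer(bins)
  width <- (hi - lo) / bins
  for (v in s) {
    b <- min(bins, floor((v - lo) / width) + 1L)
    counts[b] <- counts[b] + 1L
  }
  h <- 0
  for (cnt in counts) {
    if (cnt > 0L) {
      p <- cnt / length(s)
      h <- h - p * log2(p)
    }
  }
  h
}

# Exhaustive CFS subset search over all 2^p - 1 subsets.
oracle_exhaustive_cfs <- function(x, y) {
  p <- ncol(x)
  best_m <- -Inf
  best_s <- NULL
  for (code in seq_len(2^p - 1L)) {
    idx <- which(bitwAnd(code, 2^(seq_len(p) - 1L)) > 0)
    m <- cfs_merit(x[, idx, drop = FALSE], y)
    if (m > best_m + 1e-12) {
      best_m <- m
      best_s <- idx
    }
  }
  list(subset = best_s, merit = best_m)
}

# Small labelled recording for preprocessing tests.
make_test_recording <- function(n_ch = 3L, n_s = 1000L, fs = 250,
                                seed = 1L, label = 0L) {
  set.seed(seed)
  eeg_recording(sprintf("test%02d", seed),
                matrix(rnorm(n_ch * n_s), nrow = n_ch), fs,
                paste0("ch", seq_len(n_ch)), label = label)
}

# The published per-electrode subsets of the three-electrode montage used
# by the majority-fusion arithmetic tests.
published_subsets <- function() {
  list(
    Fp1 = c("min_amp", "mad1", "mad2"),
    Fpz = c("max_amp", "min_amp", "mad1", "mad2"),
    Fp2 = c("max_amp", "mad1", "mad2", "mean", "p2p_value")
  )
}

# Shared small separable cohort feature matrix, built once per test run.
separable_fm <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cohort <- generate_separable_cohort(synth_config(seed = 42), margin = 3)
      segs <- unlist(lapply(cohort$recordings, preprocess_recording),
                     recursive = FALSE)
      cache <<- extract_features(segs)
    }
    cache
  }
})
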