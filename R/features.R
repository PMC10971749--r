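#' The twelve temporal-domain EEG statistics
#'
#' Canonical feature-name vocabulary, in the fixed order used for all
#' feature-matrix columns: maximum amplitude, minimum amplitude, mean,
#' standard deviation, kurtosis, skewness, peak-to-peak value, peak-to-peak
#' time, mean absolute first difference, mean absolute second difference,
#' energy (mean power), and Shannon entropy of the amplitude histogram.
#'
#' @format Character vector of length 12.
#' @export
FEATURE_NAMES <- c("max_amp", "min_amp", "mean", "std", "kurtosis",
                   "skewness", "p2p_value", "p2p_time", "mad1", "mad2",
                   "energy", "entropy")

check_window <- function(s, min_n = 1L) {
  if (!is.numeric(s) || length(s) < min_n) {
    stop(sprintf("window must be numeric with at least %d samples", min_n),
         call. = FALSE)
  }
  invisible(s)
}

#' Temporal-domain statistics of one EEG window
#'
#' Each function operates on a single channel's window `s` (a numeric vector
#' of consecutive samples, microvolts). Moments use the population (1/N)
#' form throughout; kurtosis is the non-excess fourth standardized moment
#' (Gaussian reference value 3).
#'
#' @param s Numeric vector of samples (one channel, one window), microvolts.
#' @param sampling_rate Sampling rate in Hz (peak-to-peak time only).
#' @param bins Number of equal-width amplitude histogram bins (entropy only).
#' @return A numeric scalar.
#' @name temporal_features
NULL

#' @rdname temporal_features
#' @export
max_amp <- function(s) { check_window(s); max(s) }

#' @rdname temporal_features
#' @export
min_amp <- function(s) { check_window(s); min(s) }

#' @rdname temporal_features
#' @export
mean_amp <- function(s) { check_window(s); sum(s) / length(s) }

#' @rdname temporal_features
#' @export
std_amp <- function(s) {
  check_window(s, 2L)
  m <- mean(s)
  sqrt(sum((s - m)^2) / length(s))
}

#' @rdname temporal_features
#' @export
kurtosis <- function(s) {
  check_window(s, 2L)
  m <- mean(s)
  v <- mean((s - m)^2)
  if (v <= 0) {
    stop("kurtosis is undefined for a zero-variance window", call. = FALSE)
  }
  mean((s - m)^4) / v^2
}

#' @rdname temporal_features
#' @export
skewness <- function(s) {
  check_window(s, 2L)
  m <- mean(s)
  sd_p <- sqrt(mean((s - m)^2))
  if (sd_p <= 0) {
    stop("skewness is undefined for a zero-variance window", call. = FALSE)
  }
  mean(((s - m) / sd_p)^3)
}

#' @rdname temporal_features
#' @export
p2p_value <- function(s) { check_window(s); max(s) - min(s) }

#' Signed time from the global maximum to the global minimum, in seconds.
#' Ties are broken by first occurrence in time; the value is positive when
#' the maximum occurs after the minimum.
#' @rdname temporal_features
#' @export
p2p_time <- function(s, sampling_rate) {
  check_window(s, 2L)
  assert_scalar_number(sampling_rate, "sampling_rate", lower = 1e-12)
  (which.max(s) - which.min(s)) / sampling_rate
}

#' @rdname temporal_features
#' @export
mad1 <- function(s) {
  check_window(s, 2L)
  mean(abs(diff(s)))
}

#' @rdname temporal_features
#' @export
mad2 <- function(s) {
  check_window(s, 3L)
  mean(abs(diff(s, differences = 2L)))
}

#' @rdname temporal_features
#' @export
energy <- function(s) { check_window(s); mean(s^2) }

#' @rdname temporal_features
#' @export
shannon_entropy <- function(s, bins = 16L) {
  check_window(s)
  if (bins < 2L) stop("`bins` must be at least 2", call. = FALSE)
  lo <- min(s); hi <- max(s)
  if (hi - lo <= 0) return(0)  # all mass in one bin
  idx <- floor((s - lo) / (hi - lo) * bins) + 1L
  idx[idx > bins] <- bins  # the right edge belongs to the last bin
  p <- tabulate(idx, nbins = bins) / length(s)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Compute all 12 features for one channel's window, in FEATURE_NAMES order.
window_features <- function(s, sampling_rate, bins) {
  c(max_amp(s), min_amp(s), mean_amp(s), std_amp(s), kurtosis(s),
    skewness(s), p2p_value(s), p2p_time(s, sampling_rate), mad1(s),
    mad2(s), energy(s), shannon_entropy(s, bins))
}

new_feature_matrix <- function(instances, values) {
  stopifnot(is.data.frame(instances), is.matrix(values),
            nrow(instances) == nrow(values))
  structure(list(instances = instances, values = values),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d instances x %d features (%d depressed, %d healthy)\n",
              nrow(x$values), ncol(x$values),
              sum(x$instances$label == 1L), sum(x$instances$label == 0L)))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Feature column names for a channel set
#'
#' Electrode-major ordering: all 12 features of the first channel, then the
#' second, and so on, features within a channel in [FEATURE_NAMES] order.
#'
#' @param channel_names Character vector of channel names.
#' @return Character vector of `12 * length(channel_names)` column names of
#'   the form `<electrode>_<feature>`.
#' @export
feature_column_names <- function(channel_names) {
  as.vector(vapply(channel_names,
                   function(ch) paste(ch, FEATURE_NAMES, sep = "_"),
                   character(length(FEATURE_NAMES))))
}

#' Extract the feature bank from a list of segments
#'
#' Computes the 12 temporal statistics for every channel of every segment
#' and assembles the instances x features matrix: one row per window, one
#' column per (electrode, feature) pair in electrode-major order. With the
#' standard cohort (55 subjects, 40 s at 4 windows each, 3 electrodes) the
#' result is 220 x 36.
#'
#' @param segments List of segments from [segment_recording()] (possibly
#'   concatenated over subjects).
#' @param bins Histogram bin count for the entropy feature.
#' @return A `feature_matrix` with fields `instances` (data.frame:
#'   `subject_id`, `label`, `window_index`) and `values` (numeric matrix).
#' @export
extract_features <- function(segments, bins = 16L) {
  if (length(segments) == 0L) stop("no segments supplied", call. = FALSE)
  ch <- segments[[1L]]$channel_names
  fs <- segments[[1L]]$sampling_rate
  for (sg in segments) {
    if (!identical(sg$channel_names, ch) || sg$sampling_rate != fs) {
      stop("all segments must share channel set and sampling rate",
           call. = FALSE)
    }
  }
  cols <- feature_column_names(ch)
  values <- matrix(NA_real_, nrow = length(segments), ncol = length(cols),
                   dimnames = list(NULL, cols))
  for (i in seq_along(segments)) {
    sg <- segments[[i]]
    row <- tryCatch(
      unlist(lapply(seq_along(ch), function(c_i) {
        window_features(sg$signal[c_i, ], fs, bins)
      })),
      error = function(e) {
        stop(sprintf("feature extraction failed for subject %s window %d: %s",
                     sg$subject_id, sg$window_index, conditionMessage(e)),
             call. = FALSE)
      }
    )
    values[i, ] <- row
  }
  instances <- data.frame(
    subject_id = vapply(segments, `[[`, character(1), "subject_id"),
    label = vapply(segments, `[[`, integer(1), "label"),
    window_index = vapply(segments, `[[`, integer(1), "window_index"),
    stringsAsFactors = FALSE
  )
  new_feature_matrix(instances, values)
}
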