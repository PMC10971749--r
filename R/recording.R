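#' Construct an EEG recording object
#'
#' A recording holds one subject's multi-channel EEG trace as a channels x
#' samples matrix of potentials in microvolts, together with its sampling
#' rate, channel names and (optionally) a class label.
#'
#' @param subject_id Character scalar identifying the subject.
#' @param signal Numeric matrix, channels x samples, in microvolts.
#' @param sampling_rate Sampling rate in Hz (positive scalar).
#' @param channel_names Character vector of unique channel names, one per
#'   row of `signal`. Defaults to the rownames of `signal`.
#' @param label Class label: 0 = healthy control, 1 = depressed (the positive
#'   class), or `NA` when unknown.
#'
#' @return An object of class `eeg_recording`.
#' @export
#' @examples
#' rec <- eeg_recording("s01", matrix(rnorm(300), nrow = 3), 50,
#'                      c("Fp1", "Fpz", "Fp2"), label = 0L)
#' rec
eeg_recording <- function(subject_id, signal, sampling_rate,
                          channel_names = rownames(signal),
                          label = NA_integer_) {
  if (!is.matrix(signal) || !is.numeric(signal)) {
    stop("`signal` must be a numeric channels x samples matrix", call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0) {
    stop("`sampling_rate` must be a positive scalar (Hz)", call. = FALSE)
  }
  if (is.null(channel_names)) {
    stop("`channel_names` is required when `signal` has no rownames",
         call. = FALSE)
  }
  channel_names <- as.character(channel_names)
  if (length(channel_names) != nrow(signal)) {
    stop("one channel name per signal row is required", call. = FALSE)
  }
  if (anyDuplicated(channel_names)) {
    stop("channel names must be unique", call. = FALSE)
  }
  if (!is.na(label) && !label %in% c(0L, 1L)) {
    stop("`label` must be 0 (healthy), 1 (depressed) or NA", call. = FALSE)
  }
  rownames(signal) <- channel_names
  structure(
    list(
      subject_id = as.character(subject_id),
      label = if (is.na(label)) NA_integer_ else as.integer(label),
      sampling_rate = as.numeric(sampling_rate),
      channel_names = channel_names,
      signal = signal
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  dur <- ncol(x$signal) / x$sampling_rate
  cat(sprintf(
    "<eeg_recording> subject %s | label %s | %d ch x %d samples (%.6g s @ %g Hz)\n",
    x$subject_id,
    if (is.na(x$label)) "?" else as.character(x$label),
    nrow(x$signal), ncol(x$signal), dur, x$sampling_rate
  ))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An `eeg_recording`.
#' @return Numeric scalar, seconds.
#' @export
recording_duration <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  ncol(rec$signal) / rec$sampling_rate
}

# One fixed-length analysis window cut from a recording. `window_index` is
# 0-based; the source interval [start, end) is half-open, in seconds.
new_segment <- function(rec, window_index, signal, start, end) {
  structure(
    list(
      subject_id = rec$subject_id,
      label = rec$label,
      window_index = as.integer(window_index),
      sampling_rate = rec$sampling_rate,
      channel_names = rec$channel_names,
      signal = signal,
      start = start,
      end = end
    ),
    class = "eeg_segment"
  )
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf(
    "<eeg_segment> subject %s window %d | [%g, %g) s | %d ch x %d samples\n",
    x$subject_id, x$window_index, x$start, x$end,
    nrow(x$signal), ncol(x$signal)
  ))
  invisible(x)
}
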