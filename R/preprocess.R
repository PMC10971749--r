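#' Preprocessing configuration
#'
#' Bundles the parameters of the cleaning/windowing stage. Defaults follow
#' the screening protocol: 50 Hz powerline notch, window-3 moving-average
#' smoothing, the first 40 s of each recording cut into 10-s non-overlapping
#' windows (4 instances per subject).
#'
#' @param notch_freq Notch centre frequency, Hz.
#' @param notch_quality Dimensionless quality factor of the notch (centre
#'   frequency / -3 dB bandwidth).
#' @param smoothing Smoothing method, `"moving_average"` or `"median"`.
#' @param smoothing_order Odd window length of the smoother, samples.
#' @param chunk_seconds Length of the analysed chunk, seconds; must be an
#'   integer multiple of `window_seconds`.
#' @param window_seconds Analysis window length, seconds.
#' @param chunk_offset_seconds Start of the chunk within the recording,
#'   seconds from the beginning.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(notch_freq = 50, notch_quality = 30,
                              smoothing = c("moving_average", "median"),
                              smoothing_order = 3L,
                              chunk_seconds = 40, window_seconds = 10,
                              chunk_offset_seconds = 0) {
  smoothing <- match.arg(smoothing)
  assert_scalar_number(notch_freq, "notch_freq", lower = 1e-9)
  assert_scalar_number(notch_quality, "notch_quality", lower = 1e-9)
  assert_scalar_number(chunk_seconds, "chunk_seconds", lower = 1e-9)
  assert_scalar_number(window_seconds, "window_seconds", lower = 1e-9)
  assert_scalar_number(chunk_offset_seconds, "chunk_offset_seconds", lower = 0)
  if (smoothing_order %% 2L != 1L || smoothing_order < 1L) {
    stop("`smoothing_order` must be odd and >= 1", call. = FALSE)
  }
  if (abs(chunk_seconds / window_seconds -
          round(chunk_seconds / window_seconds)) > 1e-9) {
    stop("`chunk_seconds` must be an integer multiple of `window_seconds`",
         call. = FALSE)
  }
  structure(list(notch_freq = notch_freq, notch_quality = notch_quality,
                 smoothing = smoothing,
                 smoothing_order = as.integer(smoothing_order),
                 chunk_seconds = chunk_seconds,
                 window_seconds = window_seconds,
                 chunk_offset_seconds = chunk_offset_seconds),
            class = "preprocess_config")
}

#' Common average reference
#'
#' Re-references every channel to the instantaneous mean over channels:
#' the per-sample average of all electrodes is subtracted from each
#' electrode, so the output channels sum to zero at every sample.
#'
#' @param rec An [eeg_recording()] with at least two channels.
#' @return The re-referenced recording, same shape.
#' @export
average_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$signal) < 2L) {
    stop("average reference requires at least two channels", call. = FALSE)
  }
  avg <- colMeans(rec$signal)
  rec$signal <- sweep(rec$signal, 2L, avg)
  rec
}

# Biquad notch design (Audio EQ Cookbook form): unit-gain band-stop with a
# pair of zeros on the unit circle at +-w0 and poles set by the quality
# factor Q = f0 / bandwidth.
design_notch <- function(f0, fs, Q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1L], a = a / a[1L])
}

# One forward pass of a normalized biquad (a[1] = 1). The moving-average
# part is vectorized; the recursive part runs through stats::filter's C
# loop. The filter starts from the steady state of a constant input equal
# to the first sample, so constant signals pass through exactly (the notch
# has unit DC gain).
biquad_forward <- function(b, a, x) {
  n <- length(x)
  x0 <- x[1L]
  u <- b[1L] * x +
    b[2L] * c(x0, x[-n]) +
    b[3L] * c(x0, x0, x[seq_len(n - 2L)])
  as.numeric(stats::filter(u, -a[2:3], method = "recursive",
                           init = c(x0, x0)))
}

# Zero-phase (forward-backward) biquad. Ends are extended by a short odd
# reflection and each pass starts from the steady state of a constant
# input equal to its first sample, so edge transients stay localized in
# the discarded pads and constants pass through exactly.
biquad_filtfilt <- function(b, a, x) {
  n <- length(x)
  pad <- min(n - 1L, 9L)
  ext <- c(2 * x[1L] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  y <- biquad_forward(b, a, ext)
  y <- rev(biquad_forward(b, a, rev(y)))
  y[(pad + 1L):(pad + n)]
}

#' Powerline notch filter
#'
#' Applies a second-order IIR notch at `cfg$notch_freq` (default 50 Hz)
#' forward and backward for zero phase distortion, with odd-reflection end
#' padding and steady-state initialization so constants pass through
#' exactly. The narrow stopband removes the powerline tone while leaving
#' physiological rhythms (e.g. 10 Hz alpha) essentially untouched.
#'
#' @param rec An [eeg_recording()].
#' @param cfg A [preprocess_config()].
#' @return The filtered recording, same shape.
#' @export
notch_filter <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (cfg$notch_freq >= rec$sampling_rate / 2) {
    stop("notch frequency must be below the Nyquist frequency", call. = FALSE)
  }
  flt <- design_notch(cfg$notch_freq, rec$sampling_rate, cfg$notch_quality)
  for (ch in seq_len(nrow(rec$signal))) {
    rec$signal[ch, ] <- biquad_filtfilt(flt$b, flt$a, rec$signal[ch, ])
  }
  rec
}

# Centred moving average with symmetric window shrinkage at the edges: the
# i-th output averages samples within min(i-1, n-i, (order-1)/2) of i.
moving_average_shrink <- function(x, order) {
  n <- length(x)
  h <- (order - 1L) %/% 2L
  y <- as.numeric(stats::filter(x, rep(1 / order, order), sides = 2L))
  edge <- which(is.na(y))
  for (i in edge) {
    r <- min(i - 1L, n - i, h)
    y[i] <- mean(x[(i - r):(i + r)])
  }
  y
}

median_shrink <- function(x, order) {
  n <- length(x)
  h <- (order - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    r <- min(i - 1L, n - i, h)
    stats::median(x[(i - r):(i + r)])
  }, numeric(1))
}

#' Smoothing filter
#'
#' Truncates sharp transients (blinks, muscle spikes) with a centred
#' moving-average (default) or running-median smoother of odd window
#' length. Edges use symmetrically shrunk windows, so constant signals are
#' fixed points and the output length equals the input length.
#'
#' @param rec An [eeg_recording()].
#' @param cfg A [preprocess_config()]; `smoothing_order` is the window
#'   length in samples (default 3).
#' @return The smoothed recording, same shape.
#' @export
smooth_recording <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  fun <- switch(cfg$smoothing,
                moving_average = moving_average_shrink,
                median = median_shrink)
  for (ch in seq_len(nrow(rec$signal))) {
    rec$signal[ch, ] <- fun(rec$signal[ch, ], cfg$smoothing_order)
  }
  rec
}

#' Cut a recording into non-overlapping analysis windows
#'
#' Takes the `[chunk_offset, chunk_offset + chunk_seconds)` portion of the
#' recording and splits it into `chunk_seconds / window_seconds` contiguous,
#' disjoint windows (0-based indices, half-open sample intervals). No sample
#' is reused; concatenating the returned windows reproduces the chunk
#' exactly.
#'
#' @param rec An [eeg_recording()].
#' @param cfg A [preprocess_config()].
#' @return List of `eeg_segment` objects, one per window.
#' @export
segment_recording <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate
  need <- cfg$chunk_offset_seconds + cfg$chunk_seconds
  if (recording_duration(rec) < need - 1e-9) {
    stop(sprintf(
      "subject %s: recording is %.6g s but %.6g s are required for segmentation",
      rec$subject_id, recording_duration(rec), need), call. = FALSE)
  }
  w <- cfg$window_seconds * fs
  if (abs(w - round(w)) > 1e-9) {
    stop("window length must be a whole number of samples", call. = FALSE)
  }
  w <- as.integer(round(w))
  off <- as.integer(round(cfg$chunk_offset_seconds * fs))
  n_win <- as.integer(round(cfg$chunk_seconds / cfg$window_seconds))
  lapply(seq_len(n_win) - 1L, function(k) {
    i0 <- off + k * w  # 0-based start sample
    new_segment(rec, k,
                rec$signal[, (i0 + 1L):(i0 + w), drop = FALSE],
                start = i0 / fs, end = (i0 + w) / fs)
  })
}

#' Run the full cleaning/windowing stage on one recording
#'
#' Fixed stage order: average reference, powerline notch, smoothing,
#' windowing.
#'
#' @param rec An [eeg_recording()].
#' @param cfg A [preprocess_config()].
#' @return List of `eeg_segment` objects.
#' @export
preprocess_recording <- function(rec, cfg = preprocess_config()) {
  rec <- average_reference(rec)
  rec <- notch_filter(rec, cfg)
  rec <- smooth_recording(rec, cfg)
  segment_recording(rec, cfg)
}
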