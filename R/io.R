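#' Read a label manifest
#'
#' The manifest is a two-column CSV `subject_id,label` mapping each subject
#' to a class. Labels may be written `healthy`/`depressed` (case-insensitive)
#' or `0`/`1`; internally healthy = 0 (negative class) and depressed = 1
#' (the detection target).
#'
#' @param path Path to the manifest CSV.
#' @return A data.frame with columns `subject_id` (character) and `label`
#'   (integer 0/1), plus attribute `counts` with per-class totals.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "character"))
  if (!all(c("subject_id", "label") %in% names(df))) {
    stop("manifest must have columns subject_id,label", call. = FALSE)
  }
  if (anyDuplicated(df$subject_id)) {
    stop("manifest contains duplicate subject ids", call. = FALSE)
  }
  lab <- tolower(trimws(df$label))
  label <- ifelse(lab %in% c("healthy", "0"), 0L,
                  ifelse(lab %in% c("depressed", "1"), 1L, NA_integer_))
  if (anyNA(label)) {
    stop("manifest labels must be healthy/depressed or 0/1", call. = FALSE)
  }
  out <- data.frame(subject_id = df$subject_id, label = label,
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- c(healthy = sum(label == 0L),
                           depressed = sum(label == 1L))
  out
}

#' Write a label manifest
#' @param manifest A data.frame with `subject_id` and `label` columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  out <- data.frame(
    subject_id = manifest$subject_id,
    label = ifelse(manifest$label == 1L, "depressed", "healthy")
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

manifest_label <- function(manifest, subject_id) {
  i <- match(subject_id, manifest$subject_id)
  if (is.na(i)) {
    stop(sprintf("subject '%s' is not in the label manifest", subject_id),
         call. = FALSE)
  }
  manifest$label[i]
}

# ---------------------------------------------------------------------------
# EDF (European Data Format) reader/writer.
#
# Minimal single-purpose implementation of the continuous EDF layout: a
# 256-byte fixed ASCII header, 256 bytes of ASCII header per signal, then
# data records of 2-byte little-endian integers. Physical units are mapped
# to microvolts from the physical-dimension field. Annotation channels and
# EDF+ discontinuous files are out of scope.
# ---------------------------------------------------------------------------

edf_field <- function(raw, from, len) {
  trimws(rawToChar(raw[from:(from + len - 1L)]))
}

edf_unit_to_uv <- function(dim) {
  switch(tolower(dim),
         "uv" = 1, "µv" = 1, "mv" = 1e3, "v" = 1e6,
         stop(sprintf("unsupported EDF physical dimension '%s'", dim),
              call. = FALSE))
}

#' Read an EDF recording
#'
#' Reads a continuous EDF file, converts every kept signal to microvolts
#' using its physical-dimension header, restricts and reorders the channels
#' to `channels`, and attaches the class label from the manifest.
#'
#' @param path Path to an EDF file.
#' @param manifest Label manifest from [read_manifest()], or `NULL` to leave
#'   the label unset.
#' @param channels Channel names to keep, in the required order. `NULL`
#'   keeps all channels in file order.
#' @param id_source Where the subject id comes from: `"filename"` (the file
#'   stem, default — one file per subject) or `"patient"` (the EDF local
#'   patient identification field).
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, manifest = NULL, channels = NULL,
                     id_source = c("filename", "patient")) {
  id_source <- match.arg(id_source)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", 256L)
  if (length(head) < 256L) stop("truncated EDF header", call. = FALSE)
  patient <- edf_field(head, 9L, 80L)
  n_records <- as.integer(edf_field(head, 237L, 8L))
  record_dur <- as.numeric(edf_field(head, 245L, 8L))
  ns <- as.integer(edf_field(head, 253L, 4L))
  if (is.na(ns) || ns < 1L) stop("malformed EDF header (ns)", call. = FALSE)
  sig_head <- readBin(con, "raw", 256L * ns)
  fld <- function(off, len) {
    vapply(seq_len(ns) - 1L, function(i) {
      edf_field(sig_head, off * ns + i * len + 1L, len)
    }, character(1))
  }
  labels <- fld(0L, 16L)
  phys_dim <- fld(96L, 8L)  # after 16 label + 80 transducer
  phys_min <- as.numeric(fld(104L, 8L))
  phys_max <- as.numeric(fld(112L, 8L))
  dig_min <- as.numeric(fld(120L, 8L))
  dig_max <- as.numeric(fld(128L, 8L))
  spr <- as.integer(fld(216L, 8L))  # samples per record
  if (anyDuplicated(labels)) {
    stop("EDF format error: duplicate channel names", call. = FALSE)
  }
  total <- sum(spr)
  data <- matrix(NA_real_, nrow = ns, ncol = n_records * spr[1L])
  off <- rep(0L, ns)
  for (r in seq_len(n_records)) {
    block <- readBin(con, "integer", n = total, size = 2L,
                     signed = TRUE, endian = "little")
    if (length(block) < total) stop("truncated EDF data record", call. = FALSE)
    pos <- 0L
    for (s in seq_len(ns)) {
      data[s, (off[s] + 1L):(off[s] + spr[s])] <- block[(pos + 1L):(pos + spr[s])]
      off[s] <- off[s] + spr[s]
      pos <- pos + spr[s]
    }
  }
  # digital -> physical -> microvolts
  for (s in seq_len(ns)) {
    gain <- (phys_max[s] - phys_min[s]) / (dig_max[s] - dig_min[s])
    data[s, ] <- (phys_min[s] + (data[s, ] - dig_min[s]) * gain) *
      edf_unit_to_uv(phys_dim[s])
  }
  rownames(data) <- labels
  if (!is.null(channels)) {
    missing <- setdiff(channels, labels)
    if (length(missing)) {
      stop(sprintf("EDF format error: channels not present: %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    data <- data[channels, , drop = FALSE]
    labels <- channels
  }
  subject_id <- if (id_source == "patient" && nzchar(patient)) {
    strsplit(patient, " ")[[1]][1]
  } else {
    sub("\\.[^.]*$", "", basename(path))
  }
  label <- if (is.null(manifest)) NA_integer_ else
    manifest_label(manifest, subject_id)
  eeg_recording(subject_id, data, spr[1L] / record_dur, labels, label)
}

#' Write a recording to EDF
#'
#' Writes a continuous EDF file with one-second data records. Amplitudes are
#' quantized to the 16-bit range spanning the observed physical extrema, so
#' a read-back reproduces each sample to within one quantization step.
#'
#' @param rec An [eeg_recording()]; its duration must be a whole number of
#'   seconds and its sampling rate a whole number of samples per second.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate
  n <- ncol(rec$signal)
  if (fs != round(fs) || n %% fs != 0) {
    stop("EDF writer requires an integer sampling rate and whole seconds",
         call. = FALSE)
  }
  n_rec <- n %/% fs
  ns <- nrow(rec$signal)
  pad <- function(x, w) {
    x <- substr(as.character(x), 1L, w)
    formatC(x, width = -w, flag = " ")
  }
  num <- function(x, w) pad(formatC(x, digits = 6, format = "g"), w)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    pad("0", 8L), pad(rec$subject_id, 80L), pad("depscreen", 80L),
    pad("01.01.26", 8L), pad("00.00.00", 8L),
    pad(256L * (1L + ns), 8L), pad("", 44L),
    pad(n_rec, 8L), pad(1L, 8L), pad(ns, 4L)
  ), con, eos = NULL)
  pmin_v <- apply(rec$signal, 1L, min)
  pmax_v <- apply(rec$signal, 1L, max)
  flat <- pmax_v - pmin_v < 1e-12
  pmin_v[flat] <- pmin_v[flat] - 1
  pmax_v[flat] <- pmax_v[flat] + 1
  field <- function(f) writeChar(paste(f, collapse = ""), con, eos = NULL)
  field(pad(rec$channel_names, 16L))
  field(pad(rep("", ns), 80L))
  field(pad(rep("uV", ns), 8L))
  field(num(pmin_v, 8L))
  field(num(pmax_v, 8L))
  field(pad(rep(-32768L, ns), 8L))
  field(pad(rep(32767L, ns), 8L))
  field(pad(rep("", ns), 80L))
  field(pad(rep(as.integer(fs), ns), 8L))
  field(pad(rep("", ns), 32L))
  # The scaling must use the header values as parsed back (6 significant
  # digits), otherwise read-back error exceeds one quantization step.
  pmin_h <- as.numeric(trimws(num(pmin_v, 8L)))
  pmax_h <- as.numeric(trimws(num(pmax_v, 8L)))
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (s in seq_len(ns)) {
      g <- 65535 / (pmax_h[s] - pmin_h[s])
      dig <- round((rec$signal[s, idx] - pmin_h[s]) * g) - 32768
      dig <- pmin(pmax(dig, -32768), 32767)
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Delimited-matrix recordings
# ---------------------------------------------------------------------------

#' Read a recording from a delimited text matrix
#'
#' The file holds one channel per column with a header row of channel names
#' and one sample per row, in microvolts.
#'
#' @param path Path to a CSV/TSV file (delimiter auto-detected from the
#'   header line).
#' @param sampling_rate Sampling rate in Hz.
#' @param manifest Optional label manifest ([read_manifest()]).
#' @param channels Optional channel subset/order to keep.
#' @return An [eeg_recording()].
#' @export
read_matrix <- function(path, sampling_rate, manifest = NULL, channels = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty recording file", call. = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      colClasses = "numeric"),
    error = function(e) stop(sprintf("recording format error in %s: %s",
                                     path, conditionMessage(e)), call. = FALSE)
  )
  if (nrow(df) == 0L) stop("recording file has no samples", call. = FALSE)
  sig <- t(as.matrix(df))
  if (anyDuplicated(rownames(sig))) {
    stop("recording format error: duplicate channel names", call. = FALSE)
  }
  if (!is.null(channels)) {
    missing <- setdiff(channels, rownames(sig))
    if (length(missing)) {
      stop(sprintf("channels not present: %s", paste(missing, collapse = ", ")),
           call. = FALSE)
    }
    sig <- sig[channels, , drop = FALSE]
  }
  subject_id <- sub("\\.[^.]*$", "", basename(path))
  label <- if (is.null(manifest)) NA_integer_ else
    manifest_label(manifest, subject_id)
  eeg_recording(subject_id, sig, sampling_rate, rownames(sig), label)
}

#' Write a recording as a delimited text matrix
#'
#' @param rec An [eeg_recording()].
#' @param path Output path.
#' @param digits Significant digits written; read-back reproduces the written
#'   text exactly at this precision.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(rec, path, digits = 10) {
  stopifnot(inherits(rec, "eeg_recording"))
  m <- t(rec$signal)
  lines <- c(
    paste(rec$channel_names, collapse = ","),
    apply(m, 1L, function(r) {
      paste(formatC(r, digits = digits, format = "g"), collapse = ",")
    })
  )
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Feature tables
# ---------------------------------------------------------------------------

#' Write a feature matrix to CSV
#'
#' Columns are `subject_id,label` followed by the feature columns in their
#' fixed electrode-major order, one row per windowed instance.
#'
#' @param fm A [feature_matrix] as returned by [extract_features()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (nrow(fm$values) == 0L) {
    stop("refusing to write an empty feature matrix", call. = FALSE)
  }
  df <- data.frame(subject_id = fm$instances$subject_id,
                   label = fm$instances$label,
                   fm$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature matrix from CSV
#'
#' Inverse of [write_feature_table()]. Window indices are reconstructed per
#' subject in row order.
#'
#' @param path Path to a feature-table CSV.
#' @return A [feature_matrix].
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "label") %in% names(df))) {
    stop("feature table must start with subject_id,label columns",
         call. = FALSE)
  }
  vals <- as.matrix(df[, setdiff(names(df), c("subject_id", "label")),
                       drop = FALSE])
  storage.mode(vals) <- "double"
  wi <- stats::ave(seq_len(nrow(df)), df$subject_id,
                   FUN = function(i) seq_along(i) - 1L)
  new_feature_matrix(
    data.frame(subject_id = as.character(df$subject_id),
               label = as.integer(df$label),
               window_index = as.integer(wi),
               stringsAsFactors = FALSE),
    vals
  )
}
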