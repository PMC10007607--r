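# Device profiles, recordings, label streams and stream replay.

#' Construct a device profile
#'
#' A device profile describes a named EEG headset: its channel montage
#' (10-20 system labels, in the order the device emits them) and its
#' sampling rate. The sampling rate is carried explicitly so that window
#' sizing never has to be inferred from timestamps.
#'
#' @param name Identifier for the device.
#' @param channel_names Character vector of unique 10-20-system channel
#'   labels, in device order.
#' @param sampling_rate Sampling frequency in Hz (must be positive).
#' @return An object of class `device_profile` with fields `name`,
#'   `n_channels`, `sampling_rate` and `channel_names`.
#' @seealso [builtin_profile()] for the three built-in headsets.
#' @export
#' @examples
#' device_profile("toy", c("AF7", "AF8"), 128)
device_profile <- function(name, channel_names, sampling_rate) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.character(channel_names) || length(channel_names) < 1L) {
    stop("`channel_names` must be a non-empty character vector", call. = FALSE)
  }
  if (anyDuplicated(channel_names)) {
    stop("channel names must be unique", call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("`sampling_rate` must be a single positive number (Hz)", call. = FALSE)
  }
  structure(
    list(
      name = name,
      n_channels = length(channel_names),
      sampling_rate = as.numeric(sampling_rate),
      channel_names = channel_names
    ),
    class = "device_profile"
  )
}

#' @export
print.device_profile <- function(x, ...) {
  cat(sprintf(
    "<device_profile> %s: %d channels @ %g Hz [%s]\n",
    x$name, x$n_channels, x$sampling_rate,
    paste(x$channel_names, collapse = ", ")
  ))
  invisible(x)
}

#' Built-in consumer EEG device profiles
#'
#' Returns one of the three supported headset profiles:
#' \describe{
#'   \item{`muse_s`}{Muse S headband, 4 channels (AF7, AF8, TP9, TP10)
#'     at 256 Hz.}
#'   \item{`crown`}{Neurosity Crown, 8 channels (C3, C4, CP3, CP4, F5,
#'     F6, PO3, PO4) at 256 Hz.}
#'   \item{`epoc`}{Emotiv EPOC, 14 channels (AF3, F7, F3, FC5, T7, P7,
#'     O1, O2, P8, T8, FC6, F4, F8, AF4) at 128 Hz.}
#' }
#'
#' @param name One of `"muse_s"`, `"crown"`, `"epoc"`.
#' @return A [device_profile()].
#' @export
#' @examples
#' builtin_profile("muse_s")
builtin_profile <- function(name) {
  switch(name,
    muse_s = device_profile("muse_s", c("AF7", "AF8", "TP9", "TP10"), 256),
    crown = device_profile(
      "crown", c("C3", "C4", "CP3", "CP4", "F5", "F6", "PO3", "PO4"), 256
    ),
    epoc = device_profile(
      "epoc",
      c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1",
        "O2", "P8", "T8", "FC6", "F4", "F8", "AF4"),
      128
    ),
    stop(sprintf(
      "unknown device profile '%s'; available: %s",
      name, paste(builtin_profile_names(), collapse = ", ")
    ), call. = FALSE)
  )
}

#' @rdname builtin_profile
#' @export
builtin_profile_names <- function() c("muse_s", "crown", "epoc")

#' Construct an EEG recording
#'
#' A recording couples a device profile with a block of timestamped
#' multichannel samples. Timestamps are float seconds from stream start
#' and must be non-decreasing; strictly increasing unless `allow_ties`.
#'
#' @param profile A [device_profile()].
#' @param timestamps Numeric vector of sample times (seconds).
#' @param values Numeric matrix, one row per sample, one column per
#'   channel in profile order (microvolts).
#' @param allow_ties Permit duplicate timestamps (used for arrival-stamped
#'   streams whose clock has coarse resolution).
#' @return An object of class `eeg_recording` with fields `profile`,
#'   `timestamps`, `values`.
#' @export
eeg_recording <- function(profile, timestamps, values, allow_ties = FALSE) {
  stopifnot(inherits(profile, "device_profile"))
  values <- as.matrix(values)
  timestamps <- as.numeric(timestamps)
  if (nrow(values) != length(timestamps)) {
    stop("number of sample rows must match number of timestamps", call. = FALSE)
  }
  if (ncol(values) != profile$n_channels) {
    stop(sprintf(
      "recording has %d channels but profile '%s' expects %d",
      ncol(values), profile$name, profile$n_channels
    ), call. = FALSE)
  }
  if (anyNA(timestamps) || any(!is.finite(timestamps))) {
    stop("timestamps must be finite", call. = FALSE)
  }
  d <- diff(timestamps)
  if (any(d < 0)) {
    stop(sprintf(
      "timestamps must be non-decreasing (first offending row: %d)",
      which(d < 0)[1] + 1L
    ), call. = FALSE)
  }
  if (!allow_ties && any(d == 0)) {
    stop(sprintf(
      "duplicate timestamps (first offending row: %d)",
      which(d == 0)[1] + 1L
    ), call. = FALSE)
  }
  colnames(values) <- profile$channel_names
  structure(
    list(profile = profile, timestamps = timestamps, values = values),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  n <- length(x$timestamps)
  cat(sprintf(
    "<eeg_recording> %s: %d samples, %.2f s\n",
    x$profile$name, n,
    if (n > 0) x$timestamps[n] - x$timestamps[1] else 0
  ))
  invisible(x)
}

#' Number of samples in a recording
#' @param recording An [eeg_recording()].
#' @return Integer sample count.
#' @export
n_samples <- function(recording) {
  stopifnot(inherits(recording, "eeg_recording"))
  length(recording$timestamps)
}

#' Read a recording from CSV
#'
#' The recording format is a plain CSV with header
#' `timestamp,<ch1>,...,<chC>`: float seconds in the first column and one
#' microvolt column per channel. Channel columns are matched to the
#' profile *by name*, so column order in the file is free.
#'
#' @param path Path to the CSV file.
#' @param profile The [device_profile()] the file is expected to match.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, profile) {
  stopifnot(inherits(profile, "device_profile"))
  df <- utils::read.csv(path, check.names = FALSE)
  if (!identical(names(df)[1], "timestamp")) {
    stop("first column must be 'timestamp'", call. = FALSE)
  }
  have <- names(df)[-1]
  missing <- setdiff(profile$channel_names, have)
  extra <- setdiff(have, profile$channel_names)
  if (length(missing) || length(extra)) {
    stop(sprintf(
      "channel columns do not match profile '%s'%s%s",
      profile$name,
      if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")) else "",
      if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", ")) else ""
    ), call. = FALSE)
  }
  for (cn in names(df)) {
    if (!is.numeric(df[[cn]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cn]]))))[1]
      stop(sprintf(
        "non-numeric value in column '%s' (first offending row: %d)", cn,
        if (is.na(bad)) 1L else bad
      ), call. = FALSE)
    }
  }
  eeg_recording(
    profile,
    timestamps = df$timestamp,
    values = as.matrix(df[profile$channel_names])
  )
}

#' Write a recording to CSV
#'
#' Values are written with a fixed decimal precision so that
#' write/read round-trips are bit-exact at that precision.
#'
#' @param recording An [eeg_recording()].
#' @param path Output path.
#' @param digits Decimal places used for both timestamps and values.
#' @return The path, invisibly.
#' @export
write_recording <- function(recording, path, digits = 6) {
  stopifnot(inherits(recording, "eeg_recording"))
  fmt <- paste0("%.", digits, "f")
  header <- paste(c("timestamp", recording$profile$channel_names), collapse = ",")
  body <- apply(
    cbind(recording$timestamps, recording$values), 1L,
    function(r) paste(sprintf(fmt, r), collapse = ",")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Replay a recording as an ordered sample stream
#'
#' Stands in for the device's wireless transport: yields the recording's
#' samples one at a time, in timestamp order. With `paced = TRUE` the
#' iterator sleeps to approximate real-time inter-sample gaps; pacing
#' never changes the yielded content.
#'
#' @param recording A non-empty [eeg_recording()].
#' @param paced Sleep between samples to mimic real time.
#' @return An object of class `sample_stream`: call
#'   [next_sample()] on it until it returns `NULL`.
#' @export
replay_stream <- function(recording, paced = FALSE) {
  stopifnot(inherits(recording, "eeg_recording"))
  env <- new.env(parent = emptyenv())
  env$recording <- recording
  env$i <- 0L
  env$paced <- isTRUE(paced)
  structure(env, class = "sample_stream")
}

#' Pull the next sample from a stream
#'
#' @param stream A `sample_stream` from [replay_stream()].
#' @return A list with `timestamp` and named `values`, or `NULL` when the
#'   stream is exhausted.
#' @export
next_sample <- function(stream) {
  stopifnot(inherits(stream, "sample_stream"))
  n <- length(stream$recording$timestamps)
  if (stream$i >= n) return(NULL)
  i <- stream$i + 1L
  if (stream$paced && i > 1L) {
    Sys.sleep(max(
      0, stream$recording$timestamps[i] - stream$recording$timestamps[i - 1L]
    ))
  }
  stream$i <- i
  list(
    timestamp = stream$recording$timestamps[i],
    values = stream$recording$values[i, ]
  )
}

#' Collect a sample stream back into a recording
#'
#' @param stream A `sample_stream`.
#' @return An [eeg_recording()] holding all remaining samples.
#' @export
collect_stream <- function(stream) {
  stopifnot(inherits(stream, "sample_stream"))
  rec <- stream$recording
  idx <- seq_len(length(rec$timestamps))
  idx <- idx[idx > stream$i]
  stream$i <- length(rec$timestamps)
  eeg_recording(
    rec$profile, rec$timestamps[idx],
    rec$values[idx, , drop = FALSE],
    allow_ties = TRUE
  )
}

#' Stamp unstamped samples with arrival times
#'
#' Some headsets (e.g. the Muse via its phone app) deliver samples without
#' timestamps; the pipeline stamps each sample with the reading of a
#' monotone clock at arrival. The clock is injectable: pass either a
#' numeric vector (one reading per sample) or a zero-argument function
#' called once per sample.
#'
#' @param values Numeric matrix of unstamped samples (rows) by channel.
#' @param clock Numeric vector of clock readings, or a function returning
#'   one reading per call. Readings must be non-decreasing.
#' @param profile The [device_profile()] the values belong to.
#' @return An [eeg_recording()] (duplicate arrival times are tolerated,
#'   with a warning, since a coarse clock can stamp a burst identically).
#' @export
attach_arrival_timestamps <- function(values, clock, profile) {
  values <- as.matrix(values)
  n <- nrow(values)
  ts <- if (is.function(clock)) {
    vapply(seq_len(n), function(i) as.numeric(clock()), numeric(1))
  } else {
    as.numeric(clock)
  }
  if (length(ts) != n) {
    stop("clock must provide exactly one reading per sample", call. = FALSE)
  }
  if (any(diff(ts) < 0)) {
    stop(sprintf(
      "clock regression at sample %d: arrival times must be monotone",
      which(diff(ts) < 0)[1] + 1L
    ), call. = FALSE)
  }
  if (any(diff(ts) == 0)) {
    warning("duplicate arrival timestamps; downstream windowing relies on ",
            "the profile's sampling rate, not on timestamp spacing",
            call. = FALSE)
  }
  eeg_recording(profile, ts, values, allow_ties = TRUE)
}

#' Construct a stream of rating label tuples
#'
#' Each affect rating is a tuple (dimension, rating, t_start, t_end): a
#' normalized score in [0, 1] for one affect dimension, covering the time
#' interval of the stimulus it rates. In a live session the tuple becomes
#' available only at (or after) `t_end`, which is why downstream
#' evaluation treats `t_end` as the arrival order.
#'
#' @param dimension Character vector, each `"valence"` or `"arousal"`.
#' @param rating Numeric vector of normalized ratings in [0, 1].
#' @param t_start,t_end Interval covered by each rating (seconds),
#'   `t_start < t_end`.
#' @return A `data.frame` of class `label_stream`, ordered by `t_end`.
#' @export
label_tuples <- function(dimension, rating, t_start, t_end) {
  dimension <- as.character(dimension)
  bad_dim <- setdiff(unique(dimension), c("valence", "arousal"))
  if (length(bad_dim)) {
    stop(sprintf("unknown affect dimension(s): %s",
                 paste(bad_dim, collapse = ", ")), call. = FALSE)
  }
  rating <- as.numeric(rating)
  if (any(rating < 0 | rating > 1 | !is.finite(rating))) {
    stop(sprintf(
      "rating out of [0, 1] (first offending tuple: %d)",
      which(rating < 0 | rating > 1 | !is.finite(rating))[1]
    ), call. = FALSE)
  }
  t_start <- as.numeric(t_start)
  t_end <- as.numeric(t_end)
  if (any(t_start >= t_end)) {
    stop(sprintf(
      "t_start must be < t_end (first offending tuple: %d)",
      which(t_start >= t_end)[1]
    ), call. = FALSE)
  }
  df <- data.frame(
    dimension = dimension, rating = rating,
    t_start = t_start, t_end = t_end,
    stringsAsFactors = FALSE
  )
  df <- df[order(df$t_end, df$dimension), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("label_stream", "data.frame")
  df
}

#' Read a label stream from CSV
#'
#' Expects columns `dimension,rating,t_start,t_end`. Tuples are returned
#' in arrival order (by `t_end`); ratings are validated to lie in [0, 1].
#'
#' @param path Path to the CSV file.
#' @return A `label_stream` data frame; see [label_tuples()].
#' @export
read_label_stream <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("dimension", "rating", "t_start", "t_end")
  if (!all(need %in% names(df))) {
    stop(sprintf("label CSV must have columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  label_tuples(df$dimension, df$rating, df$t_start, df$t_end)
}

#' Write a label stream to CSV
#' @param labels A `label_stream` data frame.
#' @param path Output path.
#' @param digits Decimal places for ratings and times.
#' @return The path, invisibly.
#' @export
write_label_stream <- function(labels, path, digits = 6) {
  fmt <- paste0("%.", digits, "f")
  body <- sprintf(
    "%s,%s,%s,%s", labels$dimension,
    sprintf(fmt, labels$rating),
    sprintf(fmt, labels$t_start),
    sprintf(fmt, labels$t_end)
  )
  writeLines(c("dimension,rating,t_start,t_end", body), path)
  invisible(path)
}
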