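# Tumbling-window segmentation and the 16-per-channel band-power schema.

#' Canonical EEG frequency bands
#'
#' Band edges (Hz) used throughout the feature schema, as half-open
#' intervals [low, high): Delta 0.5-4, Theta 4-8, Alpha 8-16, Beta 16-32,
#' Gamma 32-45. The Alpha upper edge of 16 Hz is wider than the textbook
#' 12-13 Hz; it is kept as part of the feature-vector contract. Together
#' the five bands partition the analysis range 0.5-45 Hz.
#'
#' @return Named list of `c(low, high)` pairs in fixed order.
#' @export
eeg_bands <- function() {
  list(
    delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 16),
    beta = c(16, 32), gamma = c(32, 45)
  )
}

#' Window configuration
#'
#' A tumbling window spans `length_s` seconds, i.e. `length_s * sf`
#' samples; the product must be a whole positive number of samples.
#'
#' @param length_s Window length in seconds (the default sweep in the
#'   experiments is 1-5 s).
#' @param sf Sampling rate in Hz (take it from the device profile).
#' @return A list of class `window_config` with `length_s`, `sf`, and the
#'   per-window sample count `n_per_window`.
#' @export
window_config <- function(length_s, sf) {
  n <- length_s * sf
  if (!isTRUE(all.equal(n, round(n))) || n <= 0) {
    stop(sprintf(
      "window length %g s at %g Hz gives %g samples; need a positive integer",
      length_s, sf, n
    ), call. = FALSE)
  }
  structure(
    list(length_s = as.numeric(length_s), sf = as.numeric(sf),
         n_per_window = as.integer(round(n))),
    class = "window_config"
  )
}

#' Split a recording into tumbling windows
#'
#' Consecutive, non-overlapping blocks of exactly `length_s * sf`
#' samples; a trailing partial block is discarded. Window time stamps are
#' half-open intervals `[t, t + length_s)` anchored at the first sample
#' of each block.
#'
#' @param recording An [eeg_recording()], or a plain numeric matrix
#'   (samples by channels) if `cfg` carries the sampling rate.
#' @param cfg A [window_config()].
#' @return List of windows; each has `t_start`, `t_end` and `data` (a
#'   samples-by-channels matrix). Empty list if the recording is shorter
#'   than one window.
#' @export
tumbling_windows <- function(recording, cfg) {
  stopifnot(inherits(cfg, "window_config"))
  if (inherits(recording, "eeg_recording")) {
    values <- recording$values
    ts <- recording$timestamps
  } else {
    values <- as.matrix(recording)
    ts <- (seq_len(nrow(values)) - 1) / cfg$sf
  }
  nw <- nrow(values) %/% cfg$n_per_window
  if (nw == 0L) return(list())
  lapply(seq_len(nw), function(i) {
    from <- (i - 1L) * cfg$n_per_window + 1L
    to <- i * cfg$n_per_window
    list(
      t_start = ts[from],
      t_end = ts[from] + cfg$length_s,
      data = values[from:to, , drop = FALSE]
    )
  })
}

#' Window intervals belonging to one stimulus
#'
#' Two modes, mirroring how windows are associated with a video stimulus:
#' if the windowing can be chosen freely, windows are aligned backward
#' from the end of the stimulus (`align_end = TRUE`), giving
#' `floor((t_end - t_start) / length_s)` windows, the last ending exactly
#' at `t_end`. Otherwise (`align_end = FALSE`) pre-existing window
#' intervals are filtered to those lying wholly inside the stimulus.
#'
#' @param t_start,t_end Stimulus interval (seconds).
#' @param cfg A [window_config()].
#' @param windows For `align_end = FALSE`: a data frame with `t_start`
#'   and `t_end` columns describing existing windows.
#' @param align_end Tile backward from the stimulus end (default) or
#'   filter existing windows.
#' @return Data frame with `t_start` and `t_end`, one row per window
#'   (zero rows for a degenerate interval).
#' @export
windows_in_stimulus <- function(t_start, t_end, cfg, windows = NULL,
                                align_end = TRUE) {
  stopifnot(inherits(cfg, "window_config"))
  if (align_end) {
    k <- floor((t_end - t_start) / cfg$length_s + 1e-9)
    if (k < 1) {
      return(data.frame(t_start = numeric(0), t_end = numeric(0)))
    }
    ends <- t_end - (seq.int(k - 1, 0)) * cfg$length_s
    data.frame(t_start = ends - cfg$length_s, t_end = ends)
  } else {
    if (is.null(windows)) {
      stop("`windows` is required when align_end = FALSE", call. = FALSE)
    }
    tol <- 1e-9
    keep <- windows$t_start >= t_start - tol & windows$t_end <= t_end + tol
    windows[keep, , drop = FALSE]
  }
}

#' Shuffle labeled windows
#'
#' A seeded uniform permutation of (window, label) items; each window
#' keeps its own label. Shuffling requires the full labeled set, so it
#' applies only to the immediate (pre-recorded) setting, never during
#' live streaming. The global RNG state is left untouched.
#'
#' @param items A list or data frame of labeled items.
#' @param seed Integer seed for the permutation.
#' @return The permuted items (same type as the input).
#' @export
shuffle_labeled_windows <- function(items, seed) {
  n <- if (is.data.frame(items)) nrow(items) else length(items)
  perm <- with_preserved_rng(seed, sample.int(n))
  if (is.data.frame(items)) {
    out <- items[perm, , drop = FALSE]
    rownames(out) <- NULL
    out
  } else {
    items[perm]
  }
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodograms: the signal is cut into
#' (half-overlapping) segments, each mean-detrended, tapered with a
#' periodic Hann window, and its one-sided density-scaled periodogram
#' averaged across segments. With a 1-s window at the default segment
#' length, this degenerates to a single full-length tapered periodogram.
#'
#' @param x Numeric vector.
#' @param sf Sampling rate (Hz).
#' @param nperseg Segment length in samples (default: one second of
#'   samples, capped at the signal length).
#' @param noverlap Overlap between segments (default 50%).
#' @param detrend `"constant"` (subtract each segment's mean) or
#'   `"none"`.
#' @return List with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, sf, nperseg = min(length(x), round(sf)),
                      noverlap = floor(nperseg / 2),
                      detrend = c("constant", "none")) {
  detrend <- match.arg(detrend)
  n <- length(x)
  if (n < 1L) stop("empty signal", call. = FALSE)
  nperseg <- min(nperseg, n)
  if (noverlap >= nperseg) stop("noverlap must be < nperseg", call. = FALSE)
  step <- nperseg - noverlap
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nperseg) - 1) / nperseg)
  scale <- 1 / (sf * sum(w^2))
  nf <- nperseg %/% 2 + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    if (detrend == "constant") seg <- seg - mean(seg)
    p <- Mod(stats::fft(w * seg)[1:nf])^2 * scale
    # one-sided: double everything except DC (and Nyquist when present)
    dbl <- 2:(nf - 1L)
    if (nperseg %% 2 == 1L) dbl <- 2:nf
    p[dbl] <- 2 * p[dbl]
    acc <- acc + p
  }
  list(freq = (seq_len(nf) - 1) * sf / nperseg, psd = acc / length(starts))
}

#' Band powers of a (cleaned) window
#'
#' Integrates the Welch PSD over each of the five EEG bands plus the
#' total analysis range (0.5-45 Hz), per channel. Integration is a
#' Riemann sum of the PSD over the frequency bins whose centres fall in
#' the half-open band [low, high), so the five bands partition the total
#' range exactly.
#'
#' @param window Numeric matrix, samples by channels.
#' @param sf Sampling rate (Hz).
#' @param bands Named list of band edges, see [eeg_bands()].
#' @param ... Passed to [welch_psd()].
#' @return Numeric matrix with one row per band plus a `total` row, one
#'   column per channel; all entries non-negative.
#' @export
welch_band_powers <- function(window, sf, bands = eeg_bands(), ...) {
  window <- as.matrix(window)
  if (nrow(window) < 2L) stop("window too short for a PSD", call. = FALSE)
  total_range <- c(min(vapply(bands, `[`, numeric(1), 1L)),
                   max(vapply(bands, `[`, numeric(1), 2L)))
  out <- matrix(
    0, nrow = length(bands) + 1L, ncol = ncol(window),
    dimnames = list(c(names(bands), "total"), colnames(window))
  )
  for (j in seq_len(ncol(window))) {
    est <- welch_psd(window[, j], sf, ...)
    df <- est$freq[2] - est$freq[1]
    for (b in seq_along(bands)) {
      sel <- est$freq >= bands[[b]][1] & est$freq < bands[[b]][2]
      out[b, j] <- sum(est$psd[sel]) * df
    }
    sel <- est$freq >= total_range[1] & est$freq < total_range[2]
    out[length(bands) + 1L, j] <- sum(est$psd[sel]) * df
  }
  out
}

#' Pairwise band-power ratios
#'
#' For the fixed band order (Delta, Theta, Alpha, Beta, Gamma), returns
#' the `choose(5, 2) = 10` unordered pair ratios `band_i / band_j`
#' (`i < j` in that order). A small epsilon guards silent-channel zero
#' denominators. No log transform is applied.
#'
#' @param band_powers Numeric vector of the 5 band powers, in band order.
#' @param eps Denominator guard.
#' @return Named numeric vector of 10 ratios
#'   (`ratio_<numerator>_<denominator>`).
#' @export
power_ratios <- function(band_powers, eps = 1e-12) {
  bands <- names(eeg_bands())
  if (length(band_powers) != length(bands)) {
    stop(sprintf("expected %d band powers, got %d",
                 length(bands), length(band_powers)), call. = FALSE)
  }
  pairs <- utils::combn(length(bands), 2)
  out <- band_powers[pairs[1, ]] / (band_powers[pairs[2, ]] + eps)
  names(out) <- paste0("ratio_", bands[pairs[1, ]], "_", bands[pairs[2, ]])
  out
}

#' Feature names for a device profile
#'
#' Sixteen features per channel, channels in profile order: the five
#' band powers, the total power, then the ten pairwise ratios.
#'
#' @param profile A [device_profile()].
#' @return Character vector of length `16 * n_channels`
#'   (`<channel>_<feature>`).
#' @export
feature_names <- function(profile) {
  per_channel <- c(names(eeg_bands()), "total",
                   names(power_ratios(rep(1, 5))))
  as.vector(vapply(
    profile$channel_names,
    function(ch) paste0(ch, "_", per_channel),
    character(16)
  ))
}

#' Extract one feature vector from a preprocessed window
#'
#' Per channel: `[delta, theta, alpha, beta, gamma, total, 10 ratios]`,
#' channels concatenated in profile order, for a total of
#' `16 * n_channels` features.
#'
#' @param window Preprocessed numeric matrix, samples by channels in
#'   profile order.
#' @param profile The [device_profile()].
#' @param sf Sampling rate (defaults to the profile's).
#' @param ... Passed to [welch_band_powers()].
#' @return Named numeric vector of length `16 * n_channels`.
#' @export
extract_feature_vector <- function(window, profile, sf = profile$sampling_rate,
                                   ...) {
  window <- as.matrix(window)
  if (ncol(window) != profile$n_channels) {
    stop(sprintf("window has %d channels, profile '%s' expects %d",
                 ncol(window), profile$name, profile$n_channels),
         call. = FALSE)
  }
  bp <- welch_band_powers(window, sf, ...)
  nb <- length(eeg_bands())
  feats <- unlist(lapply(seq_len(ncol(window)), function(j) {
    c(bp[seq_len(nb), j], bp["total", j], power_ratios(bp[seq_len(nb), j]))
  }), use.names = FALSE)
  if (anyNA(feats) || any(!is.finite(feats))) {
    stop("non-finite feature values (NaN/Inf in band powers)", call. = FALSE)
  }
  names(feats) <- feature_names(profile)
  feats
}

#' Featurize a recording over stimulus-aligned tumbling windows
#'
#' Convenience driver for the offline/immediate setting: for each
#' stimulus interval, tile windows backward from the stimulus end
#' ([windows_in_stimulus()]), preprocess each window
#' ([preprocess_window()]) and extract its feature vector. When
#' `stimuli` is `NULL`, plain tumbling windows over the whole recording
#' are used instead.
#'
#' @param recording An [eeg_recording()].
#' @param cfg A [window_config()].
#' @param stimuli Optional data frame with `t_start`, `t_end` (and
#'   optionally `video_id`) rows describing stimulus intervals.
#' @param preprocess A [preprocess_config()], or `NULL` to skip
#'   preprocessing.
#' @param ... Passed to [extract_feature_vector()].
#' @return A `feature_table`: data frame with `t_start`, `t_end`,
#'   optional `video_id`, and one column per feature. The feature column
#'   names are stored in `attr(, "feature_names")`.
#' @export
featurize_recording <- function(recording, cfg, stimuli = NULL,
                                preprocess = preprocess_config(), ...) {
  stopifnot(inherits(recording, "eeg_recording"),
            inherits(cfg, "window_config"))
  profile <- recording$profile
  t0 <- recording$timestamps[1]
  sf <- cfg$sf

  intervals <- if (is.null(stimuli)) {
    wins <- tumbling_windows(recording, cfg)
    data.frame(
      t_start = vapply(wins, `[[`, numeric(1), "t_start"),
      t_end = vapply(wins, `[[`, numeric(1), "t_end")
    )
  } else {
    parts <- lapply(seq_len(nrow(stimuli)), function(i) {
      w <- windows_in_stimulus(stimuli$t_start[i], stimuli$t_end[i], cfg)
      if (nrow(w) && "video_id" %in% names(stimuli)) {
        w$video_id <- stimuli$video_id[i]
      }
      w
    })
    do.call(rbind, parts)
  }
  if (is.null(intervals) || nrow(intervals) == 0L) {
    out <- data.frame(t_start = numeric(0), t_end = numeric(0))
    attr(out, "feature_names") <- feature_names(profile)
    class(out) <- c("feature_table", "data.frame")
    return(out)
  }

  fmat <- matrix(NA_real_, nrow(intervals), 16L * profile$n_channels)
  for (i in seq_len(nrow(intervals))) {
    from <- as.integer(round((intervals$t_start[i] - t0) * sf)) + 1L
    to <- from + cfg$n_per_window - 1L
    if (from < 1L || to > nrow(recording$values)) {
      stop(sprintf(
        "window [%g, %g) falls outside the recording",
        intervals$t_start[i], intervals$t_end[i]
      ), call. = FALSE)
    }
    w <- recording$values[from:to, , drop = FALSE]
    if (!is.null(preprocess)) w <- preprocess_window(w, sf, preprocess)
    fmat[i, ] <- extract_feature_vector(w, profile, sf, ...)
  }
  colnames(fmat) <- feature_names(profile)
  out <- cbind(intervals, as.data.frame(fmat, check.names = FALSE))
  rownames(out) <- NULL
  attr(out, "feature_names") <- feature_names(profile)
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Feature matrix of a feature table
#' @param features A `feature_table` from [featurize_recording()].
#' @return Numeric matrix of the feature columns only.
#' @export
feature_matrix <- function(features) {
  fn <- attr(features, "feature_names")
  if (is.null(fn)) {
    fn <- setdiff(names(features),
                  c("t_start", "t_end", "video_id",
                    "label_valence", "label_arousal", ".label"))
  }
  as.matrix(features[, fn, drop = FALSE])
}

#' Write a feature table to CSV
#' @param features A `feature_table`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_feature_table <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_preserved_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
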