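# Seeded generator of device-realistic EEG sessions with known class
# structure and delayed label streams. The signal model: one sinusoid
# per frequency band per channel (seeded in-band frequency and phase)
# whose amplitude is multiplicatively modulated by the active stimulus's
# quadrant, plus 1/f (pink) background noise and mains-line
# interference. Ratings are emitted on the unit slider scale around the
# quadrant's nominal value, so the downstream 0.5 threshold recovers the
# intended class except when rating noise crosses it.

QUADRANTS <- c("HAHV", "HALV", "LAHV", "LALV")

quadrant_classes <- function(quadrant) {
  list(
    arousal = ifelse(substr(quadrant, 1, 1) == "H", "high", "low"),
    valence = ifelse(substr(quadrant, 3, 3) == "H", "high", "low")
  )
}

#' Default class effects for the synthetic generator
#'
#' Multiplicative per-band amplitude modulations per (dimension, class):
#' by default, high valence doubles the alpha-band amplitude and high
#' arousal scales the beta-band amplitude by 1.8, leaving all other
#' bands untouched -- a deliberately simplified, recoverable analogue of
#' band-power affect correlates.
#'
#' @return Nested list `dimension -> class -> named band multipliers`.
#' @export
default_class_effects <- function() {
  list(
    valence = list(high = c(alpha = 2.0), low = c()),
    arousal = list(high = c(beta = 1.8), low = c())
  )
}

#' Synthetic session configuration
#'
#' Defaults mirror the emulated study conditions: 16 video stimuli
#' balanced across the four valence-arousal quadrants, with durations
#' drawn from a normal with mean 86.7 s and sd 27.8 s clamped to
#' 51-150 s, recorded on a built-in device profile with 50 Hz line
#' interference.
#'
#' @param profile Device profile (default Muse S).
#' @param n_videos Number of stimuli; must be divisible by 4 so the
#'   quadrants stay balanced.
#' @param duration_mean,duration_sd,duration_range Stimulus duration
#'   model in seconds (normal, clamped to the range).
#' @param gap_s Inter-video gap (self-report time), seconds.
#' @param lead_in_s Quiet lead-in before the first video, seconds.
#' @param band_amplitudes Baseline per-band oscillation amplitudes, in
#'   microvolts.
#' @param class_effects Multiplicative per-band modulation per
#'   (dimension, class); see [default_class_effects()]. `NULL` disables
#'   all class separation (a null session).
#' @param pink_noise_scale Standard deviation of the 1/f background
#'   noise, microvolts.
#' @param line_hz,line_amplitude Mains interference frequency and
#'   amplitude.
#' @param rating_noise_sd Gaussian noise added to the nominal quadrant
#'   ratings (0.75 high / 0.25 low) before clipping to [0, 1]; this
#'   injects label noise at a controllable rate.
#' @param seed Integer seed; the session is fully determined by it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(profile = builtin_profile("muse_s"),
                         n_videos = 16, duration_mean = 86.7,
                         duration_sd = 27.8, duration_range = c(51, 150),
                         gap_s = 5, lead_in_s = 10,
                         band_amplitudes = c(delta = 20, theta = 10,
                                             alpha = 15, beta = 8,
                                             gamma = 5),
                         class_effects = default_class_effects(),
                         pink_noise_scale = 10, line_hz = 50,
                         line_amplitude = 20, rating_noise_sd = 0.05,
                         seed = 1) {
  stopifnot(inherits(profile, "device_profile"))
  if (n_videos %% 4 != 0) {
    stop("n_videos must be divisible by 4 (quadrant balance)", call. = FALSE)
  }
  if (any(band_amplitudes < 0) ||
      !setequal(names(band_amplitudes), names(eeg_bands()))) {
    stop("band_amplitudes must be non-negative and named after the five bands",
         call. = FALSE)
  }
  structure(
    list(
      profile = profile, n_videos = as.integer(n_videos),
      duration_mean = duration_mean, duration_sd = duration_sd,
      duration_range = duration_range, gap_s = gap_s,
      lead_in_s = lead_in_s,
      band_amplitudes = band_amplitudes[names(eeg_bands())],
      class_effects = class_effects,
      pink_noise_scale = pink_noise_scale, line_hz = line_hz,
      line_amplitude = line_amplitude,
      rating_noise_sd = rating_noise_sd, seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

#' Generate a balanced stimulus schedule
#'
#' `n_videos` stimuli, exactly a quarter per valence-arousal quadrant,
#' in seeded-random order, with clamped-normal durations and fixed
#' inter-video gaps.
#'
#' @param cfg A [synth_config()].
#' @return Data frame of class `stimulus_schedule`: `video_id`,
#'   `quadrant`, `valence`, `arousal`, `t_start`, `t_end`.
#' @export
generate_schedule <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_preserved_rng(cfg$seed, {
    quadrant <- sample(rep(QUADRANTS, each = cfg$n_videos / 4))
    dur <- stats::rnorm(cfg$n_videos, cfg$duration_mean, cfg$duration_sd)
    dur <- pmin(pmax(dur, cfg$duration_range[1]), cfg$duration_range[2])
    t_start <- cfg$lead_in_s +
      cumsum(c(0, utils::head(dur + cfg$gap_s, -1)))
    cls <- quadrant_classes(quadrant)
    out <- data.frame(
      video_id = seq_len(cfg$n_videos), quadrant = quadrant,
      valence = cls$valence, arousal = cls$arousal,
      t_start = t_start, t_end = t_start + dur,
      stringsAsFactors = FALSE
    )
    class(out) <- c("stimulus_schedule", "data.frame")
    out
  })
}

# Spectrally shaped white noise with 1/f amplitude profile, unit sd.
pink_noise <- function(n) {
  m <- stats::nextn(n)
  spec <- stats::fft(stats::rnorm(m))
  k <- seq_len(m) - 1
  f <- pmin(k, m - k) # two-sided bin distance from DC
  shape <- ifelse(f > 0, 1 / sqrt(f), 0)
  x <- Re(stats::fft(spec * shape, inverse = TRUE)) / m
  x <- x[seq_len(n)]
  x / stats::sd(x)
}

effect_multiplier <- function(cfg, band, video) {
  mult <- 1
  if (is.null(cfg$class_effects)) return(mult)
  for (dim in names(cfg$class_effects)) {
    cls <- video[[dim]]
    eff <- cfg$class_effects[[dim]][[cls]]
    if (!is.null(eff) && band %in% names(eff)) {
      mult <- mult * eff[[band]]
    }
  }
  mult
}

#' Generate a complete synthetic session
#'
#' Produces the recording, the delayed label stream (one tuple per
#' video per dimension, arriving at the video's end), and the
#' ground-truth schedule with the noiseless class structure.
#'
#' @param cfg A [synth_config()].
#' @return List with `recording` ([eeg_recording()]), `labels`
#'   ([label_tuples()]), and `truth` (the schedule plus the emitted
#'   ratings).
#' @export
generate_session <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  schedule <- generate_schedule(cfg)
  sf <- cfg$profile$sampling_rate
  n_ch <- cfg$profile$n_channels
  total_s <- schedule$t_end[nrow(schedule)] + cfg$gap_s
  n <- as.integer(ceiling(total_s * sf))
  t <- (seq_len(n) - 1) / sf
  bands <- eeg_bands()

  with_preserved_rng(cfg$seed + 1L, {
    # per-band, per-channel oscillator frequencies and phases
    freq <- matrix(0, length(bands), n_ch)
    phase <- matrix(0, length(bands), n_ch)
    for (b in seq_along(bands)) {
      lo <- bands[[b]][1]
      hi <- min(bands[[b]][2], 45)
      freq[b, ] <- stats::runif(n_ch, lo + 0.1 * (hi - lo),
                                hi - 0.1 * (hi - lo))
      phase[b, ] <- stats::runif(n_ch, 0, 2 * pi)
    }
    # per-band amplitude envelope (piecewise constant over stimuli)
    envelope <- matrix(1, length(bands), n)
    for (v in seq_len(nrow(schedule))) {
      sel <- t >= schedule$t_start[v] & t < schedule$t_end[v]
      video <- schedule[v, ]
      for (b in seq_along(bands)) {
        envelope[b, sel] <- effect_multiplier(cfg, names(bands)[b], video)
      }
    }
    values <- matrix(0, n, n_ch)
    for (ch in seq_len(n_ch)) {
      x <- numeric(n)
      for (b in seq_along(bands)) {
        x <- x + cfg$band_amplitudes[b] * envelope[b, ] *
          sin(2 * pi * freq[b, ch] * t + phase[b, ch])
      }
      x <- x + cfg$pink_noise_scale * pink_noise(n)
      if (cfg$line_amplitude > 0) {
        x <- x + cfg$line_amplitude *
          sin(2 * pi * cfg$line_hz * t + stats::runif(1, 0, 2 * pi))
      }
      values[, ch] <- x
    }
    # one rating per video per dimension, nominal 0.75 high / 0.25 low
    nominal <- function(cls) ifelse(cls == "high", 0.75, 0.25)
    rating_v <- pmin(pmax(
      nominal(schedule$valence) +
        stats::rnorm(cfg$n_videos, 0, cfg$rating_noise_sd), 0), 1)
    rating_a <- pmin(pmax(
      nominal(schedule$arousal) +
        stats::rnorm(cfg$n_videos, 0, cfg$rating_noise_sd), 0), 1)

    labels <- label_tuples(
      dimension = rep(c("arousal", "valence"), cfg$n_videos),
      rating = as.vector(rbind(rating_a, rating_v)),
      t_start = rep(schedule$t_start, each = 2),
      t_end = rep(schedule$t_end, each = 2)
    )
    truth <- schedule
    truth$rating_valence <- rating_v
    truth$rating_arousal <- rating_a

    list(
      recording = eeg_recording(cfg$profile, t, values),
      labels = labels,
      truth = truth
    )
  })
}

#' Write a synthetic session to disk as plain-text fixtures
#'
#' Writes `recording.csv`, `labels.csv` and `truth.json` (plus a
#' manifest) for one synthetic subject; byte-identical for identical
#' seeds.
#'
#' @param cfg A [synth_config()].
#' @param out_dir Writable output directory (created if needed).
#' @param subject Subject identifier used as a file prefix.
#' @param digits Decimal places in the CSVs.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture_set <- function(cfg, out_dir, subject = "s01", digits = 4) {
  session <- generate_session(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    recording = file.path(out_dir, paste0(subject, "_recording.csv")),
    labels = file.path(out_dir, paste0(subject, "_labels.csv")),
    truth = file.path(out_dir, paste0(subject, "_truth.json")),
    manifest = file.path(out_dir, paste0(subject, "_manifest.json"))
  )
  write_recording(session$recording, paths[["recording"]], digits = digits)
  write_label_stream(session$labels, paths[["labels"]], digits = digits)
  jsonlite::write_json(
    session$truth, paths[["truth"]],
    dataframe = "rows", digits = 6
  )
  jsonlite::write_json(
    list(
      subject = subject, profile = cfg$profile$name, seed = cfg$seed,
      n_videos = cfg$n_videos, sampling_rate = cfg$profile$sampling_rate,
      files = as.list(basename(paths[1:3]))
    ),
    paths[["manifest"]], auto_unbox = TRUE, digits = 6
  )
  invisible(paths)
}
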