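# Shared fixtures, all generated in code.

# A pure sinusoid window, samples by channels (same phase per channel).
sine_window <- function(freq, sf = 256, seconds = 1, channels = 1,
                        amplitude = 1, phase = 0) {
  t <- (seq_len(round(sf * seconds)) - 1) / sf
  matrix(rep(amplitude * sin(2 * pi * freq * t + phase), channels),
         ncol = channels)
}

rms <- function(x) sqrt(mean(x^2))

# A small, fast synthetic session for unit tests (the full-scale
# defaults are exercised in the acceptance suite).
small_session_config <- function(seed = 1, ...) {
  synth_config(
    n_videos = 4, duration_mean = 12, duration_sd = 2,
    duration_range = c(8, 16), gap_s = 2, lead_in_s = 2, seed = seed,
    ...
  )
}

# A feature table wrapper around a plain matrix, windows of length l
# tiled from t = 0 (for protocol tests that need window timestamps).
as_feature_table <- function(fm, l = 1) {
  colnames(fm) <- paste0("f", seq_len(ncol(fm)))
  out <- data.frame(
    t_start = (seq_len(nrow(fm)) - 1) * l,
    t_end = seq_len(nrow(fm)) * l
  )
  out <- cbind(out, as.data.frame(fm))
  attr(out, "feature_names") <- colnames(fm)
  class(out) <- c("feature_table", "data.frame")
  out
}

# Linearly separable stream with labels depending on two features.
separable_stream <- function(n, d = 4, seed = 1, noise = 0) {
  set.seed(seed)
  fm <- matrix(rnorm(n * d), n, d)
  margin <- fm[, 1] - fm[, 2] + noise * rnorm(n)
  list(features = fm, labels = ifelse(margin > 0, "high", "low"))
}
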