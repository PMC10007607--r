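# Tumbling windows, Welch band powers, ratios and the feature schema.

test_that("tumbling windows cut exact non-overlapping blocks", {
  profile <- device_profile("toy", c("A", "B"), 256)
  cfg <- window_config(1, 256)
  mk <- function(n) eeg_recording(profile, (0:(n - 1)) / 256,
                                  matrix(seq_len(2 * n), n, 2))
  w <- tumbling_windows(mk(256), cfg)
  expect_length(w, 1)
  expect_equal(nrow(w[[1]]$data), 256)
  expect_equal(w[[1]]$t_end - w[[1]]$t_start, 1)

  expect_length(tumbling_windows(mk(300), cfg), 1) # 44 samples discarded
  expect_length(tumbling_windows(mk(255), cfg), 0)

  w3 <- tumbling_windows(mk(768), cfg)
  expect_length(w3, 3)
  # blocks are consecutive and non-overlapping
  expect_equal(w3[[2]]$data[1, 1], w3[[1]]$data[256, 1] + 1)
  expect_error(window_config(1.001, 256), "positive integer")
})

test_that("stimulus windows tile backward from the stimulus end", {
  cfg <- window_config(1, 256)
  w <- windows_in_stimulus(10.0, 96.7, cfg)
  expect_equal(nrow(w), 86) # floor(86.7 / 1)
  expect_equal(w$t_end[86], 96.7)
  expect_equal(w$t_start[1], 96.7 - 86)
  expect_equal(w$t_end - w$t_start, rep(1, 86))

  expect_equal(nrow(windows_in_stimulus(0, 0.5, cfg)), 0)

  existing <- data.frame(t_start = c(9.5, 10.5), t_end = c(10.5, 11.5))
  kept <- windows_in_stimulus(10, 12, cfg, windows = existing,
                              align_end = FALSE)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$t_start, 10.5)
})

test_that("shuffling is a seeded permutation preserving (window, label) pairs", {
  items <- data.frame(id = 1:20, label = rep(c("low", "high"), 10))
  s1 <- shuffle_labeled_windows(items, seed = 7)
  s2 <- shuffle_labeled_windows(items, seed = 7)
  s3 <- shuffle_labeled_windows(items, seed = 8)
  expect_identical(s1, s2)
  expect_false(identical(s1$id, s3$id))
  expect_false(identical(s1$id, items$id))
  # multiset of pairs preserved: sorting recovers the original
  expect_identical(s1[order(s1$id), ]$label, items$label)
  expect_identical(shuffle_labeled_windows(items[1, ], seed = 1), items[1, ])
})

test_that("welch_psd matches an independent spectral-estimation oracle", {
  # frozen expected values from an independent Welch implementation
  # (periodic Hann taper, 50% overlap, per-segment mean detrend,
  # one-sided density scaling) on a closed-form test signal
  sf <- 256
  t2 <- (0:511) / sf
  x2 <- sin(2 * pi * 10 * t2) + 0.5 * sin(2 * pi * 25 * t2 + 1.0) +
    0.25 * sin(2 * pi * 3.3 * t2 + 0.5)
  est <- welch_psd(x2, sf)
  expect_equal(est$psd[11], 0.3333263577715745, tolerance = 1e-12)
  expect_equal(est$psd[10], 0.08333895850573884, tolerance = 1e-12)
  expect_equal(est$psd[12], 0.08333568885020003, tolerance = 1e-12)

  bp <- welch_band_powers(matrix(x2, ncol = 1), sf)
  expect_equal(unname(bp["delta", 1]), 0.020284919516346006, tolerance = 1e-10)
  expect_equal(unname(bp["theta", 1]), 0.010979342908720586, tolerance = 1e-10)
  expect_equal(unname(bp["alpha", 1]), 0.5000011532974995, tolerance = 1e-10)
  expect_equal(unname(bp["beta", 1]), 0.12500000252452115, tolerance = 1e-10)
  expect_equal(unname(bp["total", 1]), 0.6562654182645886, tolerance = 1e-10)
})

test_that("band powers behave physically", {
  # a pure 10 Hz unit sinusoid puts (almost) all its power, 0.5, in alpha
  bp <- welch_band_powers(sine_window(10), 256)
  expect_equal(unname(bp["alpha", 1]), 0.5, tolerance = 1e-6)
  others <- bp[c("delta", "theta", "beta", "gamma"), 1]
  expect_true(all(bp["alpha", 1] > 10 * others))

  expect_equal(unname(welch_band_powers(matrix(0, 256, 2), 256)),
               matrix(0, 6, 2))

  # the five bands partition the 0.5-45 Hz analysis range
  set.seed(5)
  noise <- matrix(rnorm(1024), ncol = 1)
  bpn <- welch_band_powers(noise, 256)
  expect_equal(sum(bpn[1:5, 1]), unname(bpn["total", 1]), tolerance = 1e-12)
  expect_true(all(bpn >= 0))
  expect_gte(bpn["total", 1], max(bpn[1:5, 1]))
})

test_that("power ratios cover the 10 unordered band pairs in fixed order", {
  r <- power_ratios(c(1, 1, 1, 1, 1) * 3)
  expect_length(r, 10)
  expect_equal(unname(r), rep(1, 10), tolerance = 1e-10)
  expect_equal(names(r)[1], "ratio_delta_theta")
  expect_equal(names(r)[10], "ratio_beta_gamma")

  r2 <- power_ratios(c(2, 1, 1, 1, 1))
  delta_num <- grepl("^ratio_delta_", names(r2))
  expect_equal(unname(r2[delta_num]), rep(2, 4), tolerance = 1e-10)
  expect_equal(unname(r2[!delta_num]), rep(1, 6), tolerance = 1e-10)

  # silent channel: epsilon guard keeps ratios finite
  expect_true(all(is.finite(power_ratios(rep(0, 5)))))
})

test_that("feature vectors have 16 features per channel in schema order", {
  lens <- c(muse_s = 64, crown = 128, epoc = 224)
  for (nm in names(lens)) {
    profile <- builtin_profile(nm)
    sf <- profile$sampling_rate
    set.seed(6)
    w <- matrix(rnorm(sf * profile$n_channels), sf, profile$n_channels)
    fv <- extract_feature_vector(w, profile)
    expect_length(fv, lens[[nm]])
    expect_equal(length(fv), 16 * profile$n_channels)
    expect_true(all(is.finite(fv)))
  }
  muse <- builtin_profile("muse_s")
  fn <- feature_names(muse)
  expect_equal(fn[1:6], paste0("AF7_", c("delta", "theta", "alpha",
                                         "beta", "gamma", "total")))
  expect_equal(sum(grepl("_ratio_", fn)), 4 * 10)
})

test_that("amplitude scaling multiplies powers by a^2, leaves ratios fixed", {
  set.seed(7)
  profile <- builtin_profile("muse_s")
  w <- matrix(rnorm(256 * 4), 256, 4)
  f1 <- extract_feature_vector(w, profile)
  f3 <- extract_feature_vector(3 * w, profile)
  pow <- !grepl("_ratio_", names(f1))
  expect_equal(f3[pow], 9 * f1[pow], tolerance = 1e-8)
  expect_equal(f3[!pow], f1[!pow], tolerance = 1e-8)
})

test_that("featurize_recording aligns windows with stimuli and labels them", {
  cfg <- small_session_config(seed = 21)
  s <- generate_session(cfg)
  wc <- window_config(1, cfg$profile$sampling_rate)
  stim <- stimuli_from_labels(s$labels)
  ft <- featurize_recording(s$recording, wc, stimuli = stim)
  expect_s3_class(ft, "feature_table")
  expect_equal(ncol(feature_matrix(ft)), 64)
  expect_equal(nrow(ft), sum(floor(stim$t_end - stim$t_start + 1e-9)))
  # every window ends exactly at a whole number of seconds before its
  # stimulus end
  ft <- assign_labels(ft, s$labels)
  expect_false(anyNA(ft$label_valence))
  # labeled count per video equals the aligned window count
  for (i in seq_len(nrow(stim))) {
    k <- nrow(windows_in_stimulus(stim$t_start[i], stim$t_end[i], wc))
    inside <- ft$t_start >= stim$t_start[i] - 1e-9 &
      ft$t_end <= stim$t_end[i] + 1e-9
    expect_equal(sum(inside), k)
  }
})
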