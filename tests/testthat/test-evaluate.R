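# Metric formulas, the prequential protocols, and the shuffle repeats.

test_that("accuracy and F1 follow the confusion-count formulas", {
  c1 <- structure(list(TP = 3, TN = 4, FP = 2, FN = 1, positive = "high"),
                  class = "confusion_counts")
  expect_equal(accuracy(c1), 0.7)

  c2 <- structure(list(TP = 3, TN = 0, FP = 1, FN = 1, positive = "high"),
                  class = "confusion_counts")
  expect_equal(f1_score(c2), 0.75) # 3 / (3 + 0.5 * 2)

  perfect <- confusion_counts(rep(c("high", "low"), 5),
                              rep(c("high", "low"), 5))
  expect_equal(accuracy(perfect), 1.0)
  expect_equal(f1_score(perfect), 1.0)
  expect_equal(macro_f1(perfect), 1.0)

  allwrong <- confusion_counts(c("high", "high", "low", "low"),
                               c("low", "low", "high", "high"))
  expect_equal(accuracy(allwrong), 0.0)
  expect_equal(f1_score(allwrong), 0.0)
  expect_error(accuracy(confusion_counts(character(0), character(0))),
               "no scored")
  expect_warning(
    f1_score(confusion_counts(rep("low", 3), rep("low", 3))), "undefined"
  )
})

test_that("macro F1 averages both class orientations", {
  # brute-force oracle: always-high on a balanced 100-sample stream
  predicted <- rep("high", 100)
  truth <- rep(c("high", "low"), 50)
  tab <- table(predicted = factor(predicted, c("low", "high")),
               truth = factor(truth, c("low", "high")))
  f1_of <- function(pos) {
    tp <- tab[pos, pos]
    fp <- sum(tab[pos, ]) - tp
    fn <- sum(tab[, pos]) - tp
    if (tp + 0.5 * (fp + fn) == 0) 0 else tp / (tp + 0.5 * (fp + fn))
  }
  oracle <- (f1_of("high") + f1_of("low")) / 2
  expect_equal(oracle, 1 / 3)
  ch <- confusion_counts(predicted, truth, positive = "high")
  cl <- confusion_counts(predicted, truth, positive = "low")
  expect_equal(macro_f1(ch, cl, quiet = TRUE), oracle)
})

test_that("progressive validation scores strictly before training", {
  # constant stream: the very first prediction reflects the untrained
  # model (high at 0.5), regardless of the constant label
  fm <- matrix(1, 20, 2)
  labels <- rep("low", 20)
  clf <- make_classifier("lr", 2, seed = 1)
  res <- progressive_validate(fm, labels, clf)
  expect_equal(res$predictions$predicted[1], "high")
  expect_equal(res$predictions$score[1], 0.5)
  expect_equal(nrow(res$trajectory), 20)
  # confusion totals conserve the number of scored predictions
  expect_equal(with(res$confusion, TP + TN + FP + FN), 20)

  empty <- progressive_validate(matrix(0, 0, 2), character(0),
                                make_classifier("lr", 2, seed = 1))
  expect_equal(nrow(empty$trajectory), 0)
  expect_error(
    progressive_validate(fm, rep(NA_character_, 20),
                         make_classifier("lr", 2, seed = 1)),
    "unlabeled"
  )
})

test_that("prequential accuracy rises on learnable streams", {
  stream <- separable_stream(400, d = 4, seed = 41)
  clf <- make_classifier("lr", 4, seed = 3)
  res <- progressive_validate(stream$features, stream$labels, clf)
  expect_gt(res$final$accuracy, res$trajectory$accuracy[40])
  expect_gt(res$final$accuracy, 0.8)
})

test_that("final metrics equal an offline recomputation from the log", {
  stream <- separable_stream(150, d = 4, seed = 42, noise = 1)
  clf <- make_classifier("arf", 4, n_trees = 3, seed = 4)
  res <- progressive_validate(stream$features, stream$labels, clf)
  # independent recomputation straight from the logged pairs
  tab <- table(factor(res$predictions$predicted, c("low", "high")),
               factor(res$predictions$true, c("low", "high")))
  acc <- sum(diag(tab)) / sum(tab)
  tp <- tab["high", "high"]
  f1h <- tp / (tp + 0.5 * (sum(tab["high", ]) - tp + sum(tab[, "high"]) - tp))
  tn <- tab["low", "low"]
  f1l <- tn / (tn + 0.5 * (sum(tab["low", ]) - tn + sum(tab[, "low"]) - tn))
  expect_identical(res$final$accuracy, acc)
  expect_identical(res$final$f1_high, as.numeric(f1h))
  expect_identical(res$final$f1_low, as.numeric(f1l))
  expect_identical(res$final$macro_f1, (as.numeric(f1h) + as.numeric(f1l)) / 2)
  # and the package's own audit helper agrees
  rc <- recompute_metrics(res$predictions)
  expect_identical(rc$macro_f1, res$final$macro_f1)
})

test_that("delayed validation with zero delay reproduces the immediate run", {
  stream <- separable_stream(80, d = 4, seed = 43)
  ft <- as_feature_table(stream$features)
  # one tuple per window, arriving right at the window's end
  tuples <- data.frame(
    dimension = "valence",
    rating = ifelse(stream$labels == "high", 0.75, 0.25),
    t_start = ft$t_start, t_end = ft$t_end
  )
  for (kind in c("lr", "arf")) {
    imm <- progressive_validate(
      stream$features, stream$labels,
      make_classifier(kind, 4, n_trees = 3, seed = 6)
    )
    del <- delayed_progressive_validate(
      ft, tuples, make_classifier(kind, 4, n_trees = 3, seed = 6)
    )
    expect_equal(del$trajectory[, -1], imm$trajectory[, -1])
    expect_identical(del$predictions$predicted, imm$predictions$predicted)
    expect_equal(del$n_unmatched, 0)
  }
})

test_that("delayed validation buffers a whole stimulus until its label", {
  # one video of 86 one-second windows, label arriving at the video end:
  # all 86 predictions come from the pre-label model, then 86 scoring
  # events, then 86 learn events
  set.seed(44)
  fm <- matrix(rnorm(86 * 3), 86, 3)
  ft <- as_feature_table(fm)
  ft$t_start <- ft$t_start + 10; ft$t_end <- ft$t_end + 10
  tuples <- data.frame(dimension = "arousal", rating = 0.9,
                       t_start = 10, t_end = 96)
  clf <- make_classifier("lr", 3, seed = 8)
  res <- delayed_progressive_validate(ft, tuples, clf)
  # pre-label model is untrained: every buffered prediction is 0.5/high
  expect_equal(res$predictions$score, rep(0.5, 86))
  expect_equal(res$predictions$predicted, rep("high", 86))
  expect_equal(nrow(res$trajectory), 86)
  expect_equal(unique(res$predictions$scored_at), 96)
  expect_equal(n_seen(clf), 86L)
  expect_equal(with(res$confusion, TP + TN + FP + FN), 86)
})

test_that("labels arriving late leave intervening predictions stale", {
  # video 1's label arrives only after video 2 started: video-2
  # predictions must come from the model not yet updated with video 1
  fm <- matrix(c(rep(1, 10), rep(-1, 10)), ncol = 1)
  ft <- as_feature_table(fm)
  tuples <- data.frame(
    dimension = "valence", rating = c(0.9, 0.1),
    t_start = c(0, 10), t_end = c(10, 20),
    arrival = c(15, 20.5) # video-1 label arrives mid-video-2
  )
  clf <- make_classifier("lr", 1, seed = 9)
  res <- delayed_progressive_validate(ft, tuples, clf)
  # windows 11-15 are predicted before the first label arrival: still 0.5
  expect_equal(res$predictions$score[11:15], rep(0.5, 5))
  # windows 16-20 are predicted after learning on video 1
  expect_false(any(res$predictions$score[16:20] == 0.5))
  expect_equal(res$n_unmatched, 0)
})

test_that("unmatched labels warn and unscored predictions are reported", {
  ft <- as_feature_table(matrix(0, 5, 2))
  tuples <- data.frame(dimension = "valence", rating = 0.8,
                       t_start = 100, t_end = 200)
  clf <- make_classifier("lr", 2, seed = 1)
  expect_warning(
    res <- delayed_progressive_validate(ft, tuples, clf),
    "matched no buffered"
  )
  expect_equal(res$n_unmatched, 5)
  expect_equal(nrow(res$trajectory), 0)
})

test_that("shuffled repeats are reproducible and permutation-distinct", {
  stream <- separable_stream(120, d = 4, seed = 45, noise = 0.5)
  factory <- function(seed) make_classifier("lr", 4, seed = seed)
  r1 <- shuffled_repeats(stream$features, stream$labels, factory,
                         k = 4, base_seed = 17)
  r2 <- shuffled_repeats(stream$features, stream$labels, factory,
                         k = 4, base_seed = 17)
  expect_identical(r1$per_repeat, r2$per_repeat)
  expect_equal(nrow(r1$per_repeat), 4)
  # distinct permutations give distinct (non-constant) finals
  expect_gt(r1$summary$sd_macro_f1, 0)
  expect_error(shuffled_repeats(stream$features, stream$labels, factory,
                                k = 0), "k must be")
})

test_that("holdout mode scores only the held-out fold per repeat", {
  stream <- separable_stream(200, d = 4, seed = 46)
  factory <- function(seed) make_classifier("lr", 4, seed = seed)
  h1 <- shuffled_repeats(stream$features, stream$labels, factory,
                         k = 5, base_seed = 19, mode = "holdout")
  h2 <- shuffled_repeats(stream$features, stream$labels, factory,
                         k = 5, base_seed = 19, mode = "holdout")
  expect_identical(h1$per_repeat, h2$per_repeat)
  expect_equal(h1$summary$mode, "holdout")
  # a separable concept is learnable from the other folds
  expect_gt(h1$summary$mean_accuracy, 0.85)
})
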