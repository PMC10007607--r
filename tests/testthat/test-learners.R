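# The learn-one/predict-one contract, the online logistic regression
# primitives, and the streaming ensembles.

test_that("lr_predict_one evaluates the logistic closed form", {
  p <- lr_predict_one(c(0, 0), 0, c(5, -2))
  expect_equal(p$probability, 0.5)
  expect_equal(p$class, "high") # >= 0.5 tie rule

  expect_equal(lr_predict_one(c(1, 0), 0, c(0, 5))$probability, 0.5)

  p2 <- lr_predict_one(c(2), 0, c(3))
  expect_equal(p2$probability, 1 / (1 + exp(-6)), tolerance = 1e-12)
  expect_equal(p2$class, "high")
  expect_error(lr_predict_one(c(1, 2), 0, c(1)), "same length")
})

test_that("lr_learn_one takes one SGD step on the log-loss", {
  # from zero weights, p = 0.5, residual 0.5: w <- 0.1 * 0.5 * x
  upd <- lr_learn_one(c(0, 0), 0, c(1, 0), y = 1, rate = 0.1)
  expect_equal(upd$weights, c(0.05, 0))
  expect_equal(upd$bias, 0.05)

  # saturated correct prediction: vanishing update
  upd2 <- lr_learn_one(c(10), 0, c(5), y = 1, rate = 0.1)
  expect_lt(abs(upd2$bias), 1e-10)

  # brute-force iteration drives the predicted probability up
  w <- c(0, 0); b <- 0
  for (i in 1:200) {
    s <- lr_learn_one(w, b, c(1, -1), y = 1, rate = 0.1)
    w <- s$weights; b <- s$bias
  }
  expect_gt(lr_predict_one(w, b, c(1, -1))$probability, 0.95)
})

test_that("all classifiers honor the stream-classifier contract", {
  stream <- separable_stream(60, d = 6, seed = 31)
  for (kind in c("lr", "arf", "srp")) {
    clf <- make_classifier(kind, 6, n_trees = 3, seed = 5)
    # untrained prediction is high at 0.5
    p0 <- predict_one(clf, stream$features[1, ])
    expect_equal(p0$score, 0.5)
    expect_equal(p0$class, "high")
    expect_equal(n_seen(clf), 0L)

    # predict_one never mutates: repeated predictions agree and leave
    # the subsequent trajectory unchanged
    twin <- make_classifier(kind, 6, n_trees = 3, seed = 5)
    preds <- character(30)
    for (i in 1:30) {
      for (junk in 1:3) predict_one(clf, stream$features[i + 30, ])
      preds[i] <- predict_one(clf, stream$features[i, ])$class
      learn_one(clf, stream$features[i, ], stream$labels[i])
    }
    preds_twin <- character(30)
    for (i in 1:30) {
      preds_twin[i] <- predict_one(twin, stream$features[i, ])$class
      learn_one(twin, stream$features[i, ], stream$labels[i])
    }
    expect_identical(preds, preds_twin)
    expect_equal(n_seen(clf), 30L)
    expect_error(predict_one(clf, numeric(5)), "length")
    expect_error(learn_one(clf, stream$features[1, ], "maybe"), "label")
  }
})

test_that("classifier randomness is isolated from the global RNG", {
  stream <- separable_stream(40, d = 4, seed = 32)
  run <- function() {
    clf <- make_classifier("arf", 4, n_trees = 3, seed = 9)
    for (i in 1:40) learn_one(clf, stream$features[i, ], stream$labels[i])
    vapply(1:40, function(i) predict_one(clf, stream$features[i, ])$score,
           numeric(1))
  }
  set.seed(1); s1 <- run()
  set.seed(99); draws <- rnorm(5); s2 <- run()
  expect_identical(s1, s2)
  # and the classifier does not disturb the caller's RNG stream
  set.seed(99); expect_identical(rnorm(5), draws)
})

test_that("online LR separates a linearly separable stream prequentially", {
  stream <- separable_stream(500, d = 4, seed = 33)
  clf <- make_classifier("lr", 4, seed = 2)
  res <- progressive_validate(stream$features, stream$labels, clf)
  last20 <- res$predictions[401:500, ]
  expect_gt(mean(last20$predicted == last20$true), 0.9)
})

test_that("ensembles learn a noisy nonlinear concept incrementally", {
  set.seed(34)
  n <- 400
  fm <- matrix(rnorm(n * 4), n, 4)
  labels <- ifelse(abs(fm[, 1]) > 0.67, "high", "low") # nonlinear in f1
  for (kind in c("arf", "srp")) {
    clf <- make_classifier(kind, 4, n_trees = 5, seed = 11)
    res <- progressive_validate(fm, labels, clf)
    last <- res$predictions[301:400, ]
    expect_gt(mean(last$predicted == last$true), 0.7)
  }
})

test_that("classifier state survives a save/load round trip", {
  stream <- separable_stream(50, d = 4, seed = 35)
  clf <- make_classifier("arf", 4, n_trees = 3, seed = 7)
  for (i in 1:30) learn_one(clf, stream$features[i, ], stream$labels[i])
  path <- withr::local_tempfile(fileext = ".rds")
  save_classifier(clf, path)
  back <- load_classifier(path)
  run_on <- function(c0) {
    out <- character(20)
    for (i in 31:50) {
      out[i - 30] <- predict_one(c0, stream$features[i, ])$class
      learn_one(c0, stream$features[i, ], stream$labels[i])
    }
    out
  }
  expect_identical(run_on(clf), run_on(back))
  expect_equal(n_seen(back), 50L)
})
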