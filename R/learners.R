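# Incremental classifier contract and the online logistic regression.
#
# All classifiers share the learn-one/predict-one contract:
#   predict_one(clf, x) -> list(class = "low"/"high", score = P(high))
#   learn_one(clf, x, y) -> the classifier, updated in place
# Classifiers are environments (updated in place, as a stream model must
# be); any randomness they use lives in a private RNG state seeded at
# construction, so interleaving with other code never breaks
# reproducibility. predict_one never mutates state.

CLASSES <- c("low", "high")

#' Classify one feature vector
#' @param clf A classifier from [make_classifier()].
#' @param x Numeric feature vector of the configured dimensionality.
#' @return List with `class` (`"low"`/`"high"`) and `score`, the
#'   estimated probability of the `"high"` class.
#' @export
predict_one <- function(clf, x) UseMethod("predict_one")

#' Update a classifier with one labeled feature vector
#' @param clf A classifier from [make_classifier()].
#' @param x Numeric feature vector.
#' @param y `"low"` or `"high"` (or 0/1).
#' @return The classifier, invisibly (state is updated in place).
#' @export
learn_one <- function(clf, x, y) UseMethod("learn_one")

#' Number of training examples a classifier has seen
#' @param clf A classifier.
#' @return Integer count of `learn_one` calls.
#' @export
n_seen <- function(clf) UseMethod("n_seen")

#' @export
n_seen.stream_classifier <- function(clf) clf$n_seen

check_x <- function(clf, x) {
  x <- as.numeric(x)
  if (length(x) != clf$n_features) {
    stop(sprintf("feature vector has length %d, classifier expects %d",
                 length(x), clf$n_features), call. = FALSE)
  }
  x
}

check_y <- function(y) {
  if (is.numeric(y)) y <- CLASSES[y + 1L]
  if (!y %in% CLASSES) {
    stop("class label must be 'low'/'high' (or 0/1)", call. = FALSE)
  }
  y
}

# Run `fn()` under the classifier's private RNG stream.
with_clf_rng <- function(clf, fn) {
  has_seed <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", globalenv()) else NULL
  if (is.null(clf$rng_state)) set.seed(clf$seed)
  else assign(".Random.seed", clf$rng_state, globalenv())
  on.exit({
    clf$rng_state <- get(".Random.seed", globalenv())
    if (has_seed) assign(".Random.seed", old, globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  fn()
}

logistic <- function(z) 1 / (1 + exp(-z))

#' Logistic-regression prediction for one feature vector
#'
#' The pure prediction rule: `p = logistic(w . x + b)`, classified
#' `"high"` iff `p >= 0.5` (the same tie convention as rating
#' binarization).
#'
#' @param weights Numeric weight vector, same length as `x`.
#' @param bias Scalar intercept.
#' @param x Feature vector.
#' @return List with `class` and `probability`.
#' @export
#' @examples
#' lr_predict_one(c(2), 0, c(3)) # p = logistic(6)
lr_predict_one <- function(weights, bias, x) {
  if (length(weights) != length(x)) {
    stop("weights and features must have the same length", call. = FALSE)
  }
  p <- logistic(sum(weights * x) + bias)
  list(class = if (p >= 0.5) "high" else "low", probability = p)
}

#' One stochastic-gradient step of online logistic regression
#'
#' A single SGD step on the log-loss with learning rate `rate` and no
#' regularization (a minibatch of one sample):
#' `w <- w + rate * (y - p) * x`, `b <- b + rate * (y - p)`.
#'
#' @param weights Numeric weight vector.
#' @param bias Scalar intercept.
#' @param x Feature vector.
#' @param y 0 (low) or 1 (high).
#' @param rate Learning rate (default 0.1).
#' @return List with updated `weights` and `bias`.
#' @export
lr_learn_one <- function(weights, bias, x, y, rate = 0.1) {
  if (length(weights) != length(x)) {
    stop("weights and features must have the same length", call. = FALSE)
  }
  stopifnot(y %in% c(0, 1))
  p <- logistic(sum(weights * x) + bias)
  resid <- y - p
  list(weights = weights + rate * resid * x, bias = bias + rate * resid)
}

new_lr_classifier <- function(n_features, learning_rate = 0.1, seed = 1L,
                              standardize = TRUE) {
  env <- new.env(parent = emptyenv())
  env$n_features <- as.integer(n_features)
  env$learning_rate <- learning_rate
  env$seed <- as.integer(seed)
  env$rng_state <- NULL
  env$standardize <- isTRUE(standardize)
  env$weights <- numeric(n_features)
  env$bias <- 0
  env$n_seen <- 0L
  # running per-feature mean/variance (Welford) for online standardization
  env$std_n <- 0
  env$std_mean <- numeric(n_features)
  env$std_m2 <- numeric(n_features)
  class(env) <- c("lr_classifier", "stream_classifier")
  env
}

lr_standardize <- function(clf, x) {
  if (!clf$standardize || clf$std_n < 2) return(x)
  sd <- sqrt(clf$std_m2 / (clf$std_n - 1))
  z <- (x - clf$std_mean) / ifelse(sd > 0, sd, 1)
  z[sd == 0] <- 0
  z
}

#' @export
predict_one.lr_classifier <- function(clf, x) {
  x <- check_x(clf, x)
  lr_result <- lr_predict_one(clf$weights, clf$bias, lr_standardize(clf, x))
  list(class = lr_result$class, score = lr_result$probability)
}

#' @export
learn_one.lr_classifier <- function(clf, x, y) {
  x <- check_x(clf, x)
  y <- check_y(y)
  if (clf$standardize) {
    clf$std_n <- clf$std_n + 1
    delta <- x - clf$std_mean
    clf$std_mean <- clf$std_mean + delta / clf$std_n
    clf$std_m2 <- clf$std_m2 + delta * (x - clf$std_mean)
  }
  z <- lr_standardize(clf, x)
  upd <- lr_learn_one(clf$weights, clf$bias, z,
                      y = as.integer(y == "high"), rate = clf$learning_rate)
  clf$weights <- upd$weights
  clf$bias <- upd$bias
  clf$n_seen <- clf$n_seen + 1L
  invisible(clf)
}

#' Construct an incremental classifier
#'
#' Three learners share the learn-one/predict-one contract:
#' \describe{
#'   \item{`lr`}{Online logistic regression trained by single-sample SGD
#'     on the log-loss (learning rate 0.1, no regularization), with
#'     optional online feature standardization (running mean/sd).}
#'   \item{`arf`}{Adaptive random forest: an online-bagging ensemble of
#'     incremental Hoeffding trees with per-leaf random feature subsets
#'     (`ceiling(sqrt(d))`), Poisson(6) example weighting, and a
#'     drift-detector per tree that resets it when its error rate
#'     degrades.}
#'   \item{`srp`}{Streaming random patches: the same online-bagging
#'     scheme, but each base tree is trained on a fixed random subset
#'     ("patch") of the features, re-drawn when drift resets the tree.}
#' }
#' Before any training, every classifier predicts `"high"` with score
#' 0.5 (consistent with the >= 0.5 tie rule).
#'
#' @param kind `"lr"`, `"arf"` or `"srp"`.
#' @param n_features Dimensionality of the feature vectors.
#' @param n_trees Ensemble size for `arf`/`srp`.
#' @param learning_rate SGD step size for `lr`.
#' @param seed Integer seed for the classifier's private RNG stream; two
#'   classifiers with the same configuration and seed produce identical
#'   prediction sequences on the same stream.
#' @param standardize Online feature standardization for `lr`.
#' @param ... Further arguments for the tree learners (e.g.
#'   `grace_period`, `max_depth`, `patch_fraction`).
#' @return A `stream_classifier`.
#' @export
make_classifier <- function(kind = c("lr", "arf", "srp"), n_features,
                            n_trees = 5L, learning_rate = 0.1, seed = 1L,
                            standardize = TRUE, ...) {
  kind <- match.arg(kind)
  stopifnot(n_features >= 1L)
  switch(kind,
    lr = new_lr_classifier(n_features, learning_rate, seed, standardize),
    arf = new_arf_classifier(n_features, n_trees = n_trees, seed = seed, ...),
    srp = new_srp_classifier(n_features, n_trees = n_trees, seed = seed, ...)
  )
}

#' @export
print.stream_classifier <- function(x, ...) {
  cat(sprintf("<%s> d=%d, trained on %d examples\n",
              class(x)[1], x$n_features, x$n_seen))
  invisible(x)
}

#' Save a classifier's state to a file
#'
#' Serializes the full mutable state (weights or trees, RNG stream,
#' counters) so a model trained on one part of a session can be resumed
#' on a later part, as in the live two-part protocol.
#'
#' @param clf A `stream_classifier`.
#' @param path Output path (RDS).
#' @return The path, invisibly.
#' @export
save_classifier <- function(clf, path) {
  stopifnot(inherits(clf, "stream_classifier"))
  state <- mget(ls(envir = clf, all.names = TRUE), envir = clf)
  saveRDS(list(format = 1L, classes = class(clf), state = state), path)
  invisible(path)
}

#' Restore a classifier saved with [save_classifier()]
#' @param path Path to the RDS file.
#' @return A `stream_classifier`.
#' @export
load_classifier <- function(path) {
  blob <- readRDS(path)
  if (!identical(blob$format, 1L)) {
    stop("unrecognized classifier blob format", call. = FALSE)
  }
  env <- list2env(blob$state, parent = emptyenv())
  class(env) <- blob$classes
  env
}
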