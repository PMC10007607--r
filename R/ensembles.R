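# Streaming ensembles over Hoeffding trees: adaptive random forest
# (per-leaf random feature subsets) and streaming random patches (fixed
# random feature subset per base learner). Both use online bagging --
# each tree weights each example by a Poisson(6) draw -- and a
# drift detector per tree that resets the tree (and, for patches,
# re-draws its subspace) when the tree's running error rate degrades
# significantly beyond its best observed level.

new_drift_detector <- function() {
  list(n = 0, errors = 0, p_min = Inf, s_min = Inf)
}

# Classic error-rate drift test: track p_i + s_i, flag drift when it
# exceeds the best observed p_min + 3 * s_min (after a warm-up).
drift_update <- function(dd, error) {
  dd$n <- dd$n + 1
  dd$errors <- dd$errors + error
  p <- dd$errors / dd$n
  s <- sqrt(p * (1 - p) / dd$n)
  drift <- FALSE
  if (dd$n >= 30) {
    if (p + s <= dd$p_min + dd$s_min) {
      dd$p_min <- p
      dd$s_min <- s
    } else if (p + s > dd$p_min + 3 * dd$s_min) {
      drift <- TRUE
    }
  }
  list(dd = dd, drift = drift)
}

new_bagging_ensemble <- function(n_features, n_trees, seed, lambda,
                                 grace_period, max_depth, mtry, patch_size,
                                 classes) {
  env <- new.env(parent = emptyenv())
  env$n_features <- as.integer(n_features)
  env$n_trees <- as.integer(n_trees)
  env$seed <- as.integer(seed)
  env$rng_state <- NULL
  env$lambda <- lambda
  env$grace_period <- grace_period
  env$max_depth <- max_depth
  env$mtry <- mtry
  env$patch_size <- patch_size
  env$n_seen <- 0L
  env$n_resets <- 0L
  class(env) <- c(classes, "stream_classifier")
  with_clf_rng(env, function() {
    env$members <- lapply(seq_len(n_trees), function(i) ensemble_member(env))
  })
  env
}

ensemble_member <- function(env) {
  m <- new.env(parent = emptyenv())
  m$patch <- if (is.null(env$patch_size)) NULL
             else sort(sample.int(env$n_features, env$patch_size))
  d <- if (is.null(m$patch)) env$n_features else length(m$patch)
  m$tree <- ht_new(d, grace_period = env$grace_period,
                   max_depth = env$max_depth, mtry = env$mtry)
  m$dd <- new_drift_detector()
  m
}

member_x <- function(m, x) if (is.null(m$patch)) x else x[m$patch]

ensemble_score <- function(clf, x) {
  probs <- vapply(clf$members, function(m) {
    ht_predict_prob(m$tree, member_x(m, x))
  }, numeric(1))
  mean(probs)
}

ensemble_learn <- function(clf, x, y) {
  with_clf_rng(clf, function() {
    for (m in clf$members) {
      xm <- member_x(m, x)
      pred <- if (ht_predict_prob(m$tree, xm) >= 0.5) "high" else "low"
      upd <- drift_update(m$dd, as.numeric(pred != y))
      m$dd <- upd$dd
      k <- stats::rpois(1, clf$lambda)
      if (k > 0) ht_learn(m$tree, xm, y, weight = k)
      if (upd$drift) {
        fresh <- ensemble_member(clf)
        m$patch <- fresh$patch
        m$tree <- fresh$tree
        m$dd <- fresh$dd
        clf$n_resets <- clf$n_resets + 1L
      }
    }
  })
  clf$n_seen <- clf$n_seen + 1L
  invisible(clf)
}

new_arf_classifier <- function(n_features, n_trees = 5L, seed = 1L,
                               lambda = 6, grace_period = 50,
                               max_depth = 12L, mtry = NULL) {
  if (is.null(mtry)) mtry <- max(2L, ceiling(sqrt(n_features)))
  new_bagging_ensemble(
    n_features, n_trees, seed, lambda, grace_period, max_depth,
    mtry = mtry, patch_size = NULL, classes = "arf_classifier"
  )
}

new_srp_classifier <- function(n_features, n_trees = 5L, seed = 1L,
                               lambda = 6, grace_period = 50,
                               max_depth = 12L, patch_fraction = 0.6) {
  patch_size <- max(2L, round(patch_fraction * n_features))
  new_bagging_ensemble(
    n_features, n_trees, seed, lambda, grace_period, max_depth,
    mtry = NULL, patch_size = patch_size, classes = "srp_classifier"
  )
}

#' @export
predict_one.arf_classifier <- function(clf, x) {
  x <- check_x(clf, x)
  p <- ensemble_score(clf, x)
  list(class = if (p >= 0.5) "high" else "low", score = p)
}

#' @export
predict_one.srp_classifier <- predict_one.arf_classifier

#' @export
learn_one.arf_classifier <- function(clf, x, y) {
  x <- check_x(clf, x)
  ensemble_learn(clf, x, check_y(y))
}

#' @export
learn_one.srp_classifier <- learn_one.arf_classifier
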