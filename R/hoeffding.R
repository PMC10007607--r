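# Incremental Hoeffding tree for binary classification on numeric
# features. Leaves keep per-class Gaussian summaries (weighted Welford)
# of each candidate feature; a leaf splits when the Hoeffding bound says
# the best candidate split's information gain beats the runner-up with
# the configured confidence (or the two are within the tie threshold).
# This is the classic VFDT scheme with Gaussian numeric attribute
# observers; it is the base learner the streaming ensembles grow.

ht_new <- function(n_features, grace_period = 50, split_confidence = 1e-6,
                   tie_threshold = 0.05, max_depth = 12L, mtry = NULL,
                   n_candidates = 10L) {
  ht <- new.env(parent = emptyenv())
  ht$n_features <- as.integer(n_features)
  ht$grace_period <- grace_period
  ht$split_confidence <- split_confidence
  ht$tie_threshold <- tie_threshold
  ht$max_depth <- as.integer(max_depth)
  ht$mtry <- if (is.null(mtry)) NULL else as.integer(mtry)
  ht$n_candidates <- as.integer(n_candidates)
  ht$root <- ht_new_leaf(ht, depth = 0L)
  ht
}

# Leaves draw their candidate-feature subset at creation time (the
# per-leaf random subspace used by the adaptive random forest). Must be
# called under the owning classifier's RNG.
ht_new_leaf <- function(ht, depth) {
  node <- new.env(parent = emptyenv())
  node$is_leaf <- TRUE
  node$depth <- depth
  node$counts <- c(low = 0, high = 0)
  node$feat_idx <- if (is.null(ht$mtry) || ht$mtry >= ht$n_features) {
    seq_len(ht$n_features)
  } else {
    sort(sample.int(ht$n_features, ht$mtry))
  }
  k <- length(node$feat_idx)
  node$wsum <- matrix(0, k, 2)
  node$mean <- matrix(0, k, 2)
  node$m2 <- matrix(0, k, 2)
  node$fmin <- rep(Inf, k)
  node$fmax <- rep(-Inf, k)
  node$weight_at_last_attempt <- 0
  node
}

ht_sink <- function(ht, x) {
  node <- ht$root
  while (!node$is_leaf) {
    node <- if (x[node$feature] <= node$threshold) node$left else node$right
  }
  node
}

binary_entropy <- function(w) {
  tot <- sum(w)
  if (tot <= 0) return(0)
  p <- w[w > 0] / tot
  -sum(p * log2(p))
}

ht_learn <- function(ht, x, y, weight = 1) {
  node <- ht_sink(ht, x)
  ci <- if (y == "high") 2L else 1L
  node$counts[ci] <- node$counts[ci] + weight
  v <- x[node$feat_idx]
  w0 <- node$wsum[, ci]
  w1 <- w0 + weight
  delta <- v - node$mean[, ci]
  node$mean[, ci] <- node$mean[, ci] + weight * delta / w1
  node$m2[, ci] <- node$m2[, ci] + weight * delta * (v - node$mean[, ci])
  node$wsum[, ci] <- w1
  node$fmin <- pmin(node$fmin, v)
  node$fmax <- pmax(node$fmax, v)

  tot <- sum(node$counts)
  if (all(node$counts > 0) && node$depth < ht$max_depth &&
      tot - node$weight_at_last_attempt >= ht$grace_period) {
    node$weight_at_last_attempt <- tot
    ht_attempt_split(ht, node)
  }
  invisible(ht)
}

# Estimate the class weights falling on each side of a threshold from
# the per-class Gaussian summaries.
ht_best_split_for_feature <- function(ht, node, k) {
  lo <- node$fmin[k]
  hi <- node$fmax[k]
  if (!is.finite(lo) || hi <= lo) return(NULL)
  cand <- seq(lo, hi, length.out = ht$n_candidates + 2L)
  cand <- cand[-c(1L, length(cand))]
  h0 <- binary_entropy(node$counts)
  best <- NULL
  for (t in cand) {
    wl <- numeric(2)
    for (ci in 1:2) {
      w <- node$wsum[k, ci]
      if (w <= 0) next
      s <- if (w > 1) sqrt(max(node$m2[k, ci], 0) / (w - 1)) else 0
      frac <- if (s > 0) stats::pnorm(t, node$mean[k, ci], s)
              else as.numeric(node$mean[k, ci] <= t)
      wl[ci] <- w * frac
    }
    wr <- node$counts - wl
    tot <- sum(node$counts)
    rem <- (sum(wl) * binary_entropy(wl) + sum(wr) * binary_entropy(wr)) / tot
    gain <- h0 - rem
    if (is.null(best) || gain > best$gain) {
      best <- list(gain = gain, threshold = t)
    }
  }
  best
}

ht_attempt_split <- function(ht, node) {
  gains <- lapply(seq_along(node$feat_idx), function(k) {
    ht_best_split_for_feature(ht, node, k)
  })
  ok <- !vapply(gains, is.null, logical(1))
  if (!any(ok)) return(invisible(NULL))
  g <- vapply(gains[ok], `[[`, numeric(1), "gain")
  idx <- which(ok)
  ord <- order(g, decreasing = TRUE)
  g1 <- g[ord[1]]
  g2 <- if (length(ord) > 1L) g[ord[2]] else 0
  w <- sum(node$counts)
  # Hoeffding bound for the gain estimate; binary entropy has range 1 bit
  eps <- sqrt(log(1 / ht$split_confidence) / (2 * w))
  if (g1 > 0 && (g1 - g2 > eps || eps < ht$tie_threshold)) {
    k <- idx[ord[1]]
    node$is_leaf <- FALSE
    node$feature <- node$feat_idx[k]
    node$threshold <- gains[[k]]$threshold
    node$left <- ht_new_leaf(ht, node$depth + 1L)
    node$right <- ht_new_leaf(ht, node$depth + 1L)
    # release the leaf summaries
    node$wsum <- node$mean <- node$m2 <- NULL
    node$fmin <- node$fmax <- NULL
  }
  invisible(NULL)
}

# Laplace-smoothed probability of the "high" class at the sunk leaf.
ht_predict_prob <- function(ht, x) {
  node <- ht_sink(ht, x)
  (node$counts[["high"]] + 1) / (sum(node$counts) + 2)
}
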