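# Confusion accounting, accuracy / F1, progressive (test-then-train)
# validation, and delayed progressive validation with a prediction
# buffer.

#' Confusion counts
#'
#' TP/TN/FP/FN bookkeeping relative to a declared positive class.
#'
#' @param predicted,truth Character vectors of `"low"`/`"high"`.
#' @param positive The class counted as positive (default `"high"`).
#' @return A list of class `confusion_counts` with fields `TP`, `TN`,
#'   `FP`, `FN` and `positive`.
#' @export
confusion_counts <- function(predicted, truth, positive = "high") {
  stopifnot(length(predicted) == length(truth))
  structure(
    list(
      TP = sum(predicted == positive & truth == positive),
      TN = sum(predicted != positive & truth != positive),
      FP = sum(predicted == positive & truth != positive),
      FN = sum(predicted != positive & truth == positive),
      positive = positive
    ),
    class = "confusion_counts"
  )
}

confusion_total <- function(c) c$TP + c$TN + c$FP + c$FN

# Swap the positive class without re-scoring.
confusion_flip <- function(c) {
  structure(
    list(TP = c$TN, TN = c$TP, FP = c$FN, FN = c$FP,
         positive = setdiff(c("low", "high"), c$positive)),
    class = "confusion_counts"
  )
}

#' Accuracy from confusion counts
#'
#' `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param counts A [confusion_counts()] object.
#' @return Fraction in [0, 1].
#' @export
accuracy <- function(counts) {
  tot <- confusion_total(counts)
  if (tot == 0) stop("no scored predictions", call. = FALSE)
  (counts$TP + counts$TN) / tot
}

#' F1 score from confusion counts
#'
#' `TP / (TP + (FP + FN) / 2)`. When the score is undefined because the
#' positive class never occurs in either predictions or truth
#' (`TP + FP + FN == 0`), it is defined as 0 with a warning.
#'
#' @param counts A [confusion_counts()] object.
#' @param quiet Suppress the undefined-score warning.
#' @return Score in [0, 1].
#' @export
f1_score <- function(counts, quiet = FALSE) {
  denom <- counts$TP + 0.5 * (counts$FP + counts$FN)
  if (denom == 0) {
    if (!quiet) {
      warning("F1 undefined (no positives anywhere); returning 0",
              call. = FALSE)
    }
    return(0)
  }
  counts$TP / denom
}

#' Macro F1 across the two classes
#'
#' Arithmetic mean of the F1 with `"high"` as positive and the F1 with
#' `"low"` as positive, both computed from the same predictions.
#'
#' @param counts_high [confusion_counts()] with positive `"high"`.
#' @param counts_low [confusion_counts()] with positive `"low"` from the
#'   same predictions; defaults to the class-swapped view of
#'   `counts_high`.
#' @param quiet Suppress undefined-F1 warnings.
#' @return Score in [0, 1].
#' @export
macro_f1 <- function(counts_high, counts_low = confusion_flip(counts_high),
                     quiet = FALSE) {
  (f1_score(counts_high, quiet) + f1_score(counts_low, quiet)) / 2
}

# Incremental confusion updates shared by both protocols. Returns the
# trajectory metrics row for the current state.
metrics_row <- function(c_high) {
  c_low <- confusion_flip(c_high)
  f1h <- f1_score(c_high, quiet = TRUE)
  f1l <- f1_score(c_low, quiet = TRUE)
  c(accuracy = accuracy(c_high), f1_high = f1h, f1_low = f1l,
    macro_f1 = (f1h + f1l) / 2)
}

new_trajectory <- function(trajectory, predictions, c_high, extra = list()) {
  structure(
    c(list(
      trajectory = trajectory, predictions = predictions,
      confusion = c_high,
      final = if (nrow(trajectory)) as.list(trajectory[nrow(trajectory), ])
              else list(accuracy = NA_real_, f1_high = NA_real_,
                        f1_low = NA_real_, macro_f1 = NA_real_)
    ), extra),
    class = "metric_trajectory"
  )
}

#' @export
print.metric_trajectory <- function(x, ...) {
  n <- nrow(x$trajectory)
  if (n == 0) {
    cat("<metric_trajectory> empty\n")
  } else {
    cat(sprintf(
      "<metric_trajectory> %d scored predictions; final accuracy %.3f, macro F1 %.3f\n",
      n, x$final$accuracy, x$final$macro_f1
    ))
  }
  invisible(x)
}

#' Progressive (test-then-train) validation
#'
#' For each labeled feature vector, in stream order: the model first
#' classifies it (the test step), the prediction is scored against the
#' true label and the running metrics updated, and only then is the
#' model trained on it. Every sample therefore serves for both
#' validation and training without corrupting the evaluation.
#'
#' @param features Numeric matrix of feature vectors (rows in stream
#'   order), or a `feature_table`.
#' @param labels Character vector of `"low"`/`"high"`, one per row; no
#'   `NA`s allowed.
#' @param clf A `stream_classifier`; it is updated in place.
#' @return A `metric_trajectory`: per-update `trajectory` data frame
#'   (`index`, `accuracy`, `f1_high`, `f1_low`, `macro_f1`), the
#'   `predictions` log, the final `confusion` counts, and `final`
#'   metrics.
#' @export
progressive_validate <- function(features, labels, clf) {
  if (is.data.frame(features)) features <- feature_matrix(features)
  n <- nrow(features)
  if (length(labels) != n) {
    stop("need exactly one label per feature vector", call. = FALSE)
  }
  if (n > 0 && anyNA(labels)) {
    stop("unlabeled vector in a progressive validation stream", call. = FALSE)
  }
  pred <- character(n)
  score <- numeric(n)
  traj <- matrix(NA_real_, n, 4,
                 dimnames = list(NULL, c("accuracy", "f1_high",
                                         "f1_low", "macro_f1")))
  c_high <- confusion_counts(character(0), character(0))
  for (i in seq_len(n)) {
    p <- predict_one(clf, features[i, ])
    pred[i] <- p$class
    score[i] <- p$score
    if (p$class == "high" && labels[i] == "high") c_high$TP <- c_high$TP + 1
    else if (p$class == "low" && labels[i] == "low") c_high$TN <- c_high$TN + 1
    else if (p$class == "high") c_high$FP <- c_high$FP + 1
    else c_high$FN <- c_high$FN + 1
    traj[i, ] <- metrics_row(c_high)
    learn_one(clf, features[i, ], labels[i])
  }
  new_trajectory(
    trajectory = data.frame(index = seq_len(n), traj),
    predictions = data.frame(
      index = seq_len(n), predicted = pred, score = score, true = labels,
      stringsAsFactors = FALSE
    ),
    c_high = c_high
  )
}

#' Delayed progressive validation
#'
#' The live-protocol variant: feature vectors are classified on arrival
#' with the current model and buffered; a rating tuple's arrival scores
#' every buffered prediction whose window lies inside the tuple's
#' interval (one metric update per buffered prediction), after which the
#' model is trained on those samples in window order. Predictions made
#' after a tuple's arrival therefore use the updated model, and in the
#' zero-delay limit the procedure reduces exactly to
#' [progressive_validate()].
#'
#' @param features A `feature_table` whose rows carry `t_start` /
#'   `t_end` (stream order by `t_end`).
#' @param tuples A `label_stream` for a single dimension (see
#'   [label_tuples()]); an optional `arrival` column overrides the
#'   default label arrival time `t_end` (used to induce artificial
#'   delays).
#' @param clf A `stream_classifier`, updated in place.
#' @param dimension Which dimension's tuples to use when `tuples` holds
#'   both.
#' @param threshold Rating binarization threshold.
#' @return A `metric_trajectory`; its `predictions` log adds `t_start`,
#'   `t_end` and `scored_at` (label arrival time), and `n_unmatched`
#'   counts buffered predictions whose label never arrived.
#' @export
delayed_progressive_validate <- function(features, tuples, clf,
                                         dimension = NULL, threshold = 0.5) {
  if (!is.null(dimension)) {
    tuples <- tuples[tuples$dimension == dimension, , drop = FALSE]
  }
  if (length(unique(tuples$dimension)) > 1L) {
    stop("tuples span several dimensions; pass `dimension`", call. = FALSE)
  }
  fmat <- feature_matrix(features)
  nf <- nrow(fmat)
  arrival <- if ("arrival" %in% names(tuples)) tuples$arrival else tuples$t_end
  # event schedule: windows arrive at their t_end, labels at `arrival`;
  # at equal times the window precedes the label that covers it
  ev <- rbind(
    data.frame(time = features$t_end, type = 1L, idx = seq_len(nf)),
    data.frame(time = arrival, type = 2L, idx = seq_len(nrow(tuples)))
  )
  ev <- ev[order(ev$time, ev$type, ev$idx), , drop = FALSE]

  pred <- character(nf)
  score <- numeric(nf)
  scored_at <- rep(NA_real_, nf)
  in_buffer <- logical(nf)
  traj_idx <- integer(0)
  traj <- NULL
  c_high <- confusion_counts(character(0), character(0))
  truth <- rep(NA_character_, nf)
  tol <- 1e-9

  for (e in seq_len(nrow(ev))) {
    if (ev$type[e] == 1L) {
      i <- ev$idx[e]
      p <- predict_one(clf, fmat[i, ])
      pred[i] <- p$class
      score[i] <- p$score
      in_buffer[i] <- TRUE
    } else {
      j <- ev$idx[e]
      lab <- binarize_rating(tuples$rating[j], threshold)
      hit <- which(in_buffer &
                     features$t_start >= tuples$t_start[j] - tol &
                     features$t_end <= tuples$t_end[j] + tol)
      if (length(hit) == 0L) {
        warning(sprintf(
          "label tuple [%g, %g] matched no buffered predictions",
          tuples$t_start[j], tuples$t_end[j]
        ), call. = FALSE)
        next
      }
      hit <- hit[order(features$t_end[hit])]
      for (i in hit) {
        if (pred[i] == "high" && lab == "high") c_high$TP <- c_high$TP + 1
        else if (pred[i] == "low" && lab == "low") c_high$TN <- c_high$TN + 1
        else if (pred[i] == "high") c_high$FP <- c_high$FP + 1
        else c_high$FN <- c_high$FN + 1
        traj <- rbind(traj, metrics_row(c_high))
        traj_idx <- c(traj_idx, i)
        truth[i] <- lab
        scored_at[i] <- ev$time[e]
        in_buffer[i] <- FALSE
      }
      for (i in hit) learn_one(clf, fmat[i, ], lab)
    }
  }
  trajectory <- if (is.null(traj)) {
    data.frame(index = integer(0), accuracy = numeric(0),
               f1_high = numeric(0), f1_low = numeric(0),
               macro_f1 = numeric(0))
  } else {
    data.frame(index = seq_len(nrow(traj)), traj, row.names = NULL)
  }
  new_trajectory(
    trajectory = trajectory,
    predictions = data.frame(
      index = seq_len(nf), t_start = features$t_start,
      t_end = features$t_end, predicted = pred, score = score,
      true = truth, scored_at = scored_at, stringsAsFactors = FALSE
    ),
    c_high = c_high,
    extra = list(n_unmatched = sum(in_buffer))
  )
}

#' Repeated seeded shuffle-and-validate runs
#'
#' Runs [progressive_validate()] `k` times, each on a freshly seeded
#' uniform shuffle of the full labeled window set with a fresh
#' classifier, and reports per-repeat and aggregated final metrics.
#' Every sample is still both tested and trained on within each repeat;
#' the repeats quantify the variability induced by stream order and
#' classifier randomness.
#'
#' @param features Feature matrix or `feature_table` (full labeled set).
#' @param labels Character labels, one per row.
#' @param clf_factory Function `function(seed)` returning a fresh
#'   `stream_classifier`.
#' @param k Number of repeats (default 10).
#' @param base_seed Base integer seed; repeat `r` uses `base_seed + r`
#'   for both its shuffle and its classifier.
#' @param mode `"prequential"` (default): each repeat is a full
#'   test-then-train pass over its own shuffle, so every sample serves
#'   both roles. `"holdout"`: a classic k-fold comparison mode in which
#'   one shuffled fold is held out per repeat, the classifier is trained
#'   prequentially on the remaining folds, and only the held-out fold is
#'   scored (without further training).
#' @return A list of class `shuffled_repeats` with `per_repeat` (data
#'   frame of final metrics per repeat) and `summary` (mean and sd of
#'   accuracy and macro F1).
#' @export
shuffled_repeats <- function(features, labels, clf_factory, k = 10,
                             base_seed = 1,
                             mode = c("prequential", "holdout")) {
  mode <- match.arg(mode)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (is.data.frame(features)) features <- feature_matrix(features)
  n <- nrow(features)
  fold <- if (mode == "holdout") {
    with_preserved_rng(base_seed, sample(rep_len(seq_len(k), n)))
  }
  rows <- vector("list", k)
  for (r in seq_len(k)) {
    seed <- base_seed + r
    clf <- clf_factory(seed)
    if (mode == "prequential") {
      perm <- with_preserved_rng(seed, sample.int(n))
      res <- progressive_validate(features[perm, , drop = FALSE],
                                  labels[perm], clf)
      final <- res$final
    } else {
      train <- which(fold != r)
      test <- which(fold == r)
      perm <- train[with_preserved_rng(seed, sample.int(length(train)))]
      for (i in perm) learn_one(clf, features[i, ], labels[i])
      pred <- vapply(test, function(i) predict_one(clf, features[i, ])$class,
                     character(1))
      final <- recompute_metrics(
        data.frame(predicted = pred, true = labels[test])
      )
    }
    rows[[r]] <- data.frame(
      repeat_id = r, seed = seed,
      accuracy = final$accuracy, f1_high = final$f1_high,
      f1_low = final$f1_low, macro_f1 = final$macro_f1
    )
  }
  per_repeat <- do.call(rbind, rows)
  structure(
    list(
      per_repeat = per_repeat,
      summary = list(
        mean_accuracy = mean(per_repeat$accuracy),
        sd_accuracy = stats::sd(per_repeat$accuracy),
        mean_macro_f1 = mean(per_repeat$macro_f1),
        sd_macro_f1 = stats::sd(per_repeat$macro_f1),
        k = k, mode = mode
      )
    ),
    class = "shuffled_repeats"
  )
}

#' @export
print.shuffled_repeats <- function(x, ...) {
  cat(sprintf(
    "<shuffled_repeats> k=%d: macro F1 %.3f +/- %.3f, accuracy %.3f +/- %.3f\n",
    x$summary$k, x$summary$mean_macro_f1, x$summary$sd_macro_f1,
    x$summary$mean_accuracy, x$summary$sd_accuracy
  ))
  invisible(x)
}

#' Recompute final metrics from a predictions log
#'
#' Offline recomputation of accuracy and the three F1 views from the
#' logged (prediction, truth) pairs; used to audit that a run's
#' incrementally maintained trajectory ends at exactly the same values.
#'
#' @param predictions A predictions log from a `metric_trajectory`
#'   (rows with no truth, i.e. never-scored buffered predictions, are
#'   ignored).
#' @return List with `accuracy`, `f1_high`, `f1_low`, `macro_f1`.
#' @export
recompute_metrics <- function(predictions) {
  scored <- predictions[!is.na(predictions$true), , drop = FALSE]
  ch <- confusion_counts(scored$predicted, scored$true, positive = "high")
  cl <- confusion_counts(scored$predicted, scored$true, positive = "low")
  list(
    accuracy = accuracy(ch),
    f1_high = f1_score(ch, quiet = TRUE),
    f1_low = f1_score(cl, quiet = TRUE),
    macro_f1 = macro_f1(ch, cl, quiet = TRUE)
  )
}
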