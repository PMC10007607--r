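# Experiment orchestration: the immediate-label setting, the
# window-length sweep, and the delayed-label (live) protocol. All runs
# are single-process event-time simulations; wall-clock pacing never
# affects results. Valence and arousal are classified by independent
# models sharing the same features.

#' Recover stimulus intervals from a label stream
#'
#' Each video contributes one tuple per dimension over the same
#' interval; the unique intervals, in time order, are the stimuli.
#'
#' @param labels A `label_stream`.
#' @return Data frame with `video_id`, `t_start`, `t_end`.
#' @export
stimuli_from_labels <- function(labels) {
  iv <- unique(labels[, c("t_start", "t_end")])
  iv <- iv[order(iv$t_start), , drop = FALSE]
  rownames(iv) <- NULL
  cbind(video_id = seq_len(nrow(iv)), iv)
}

run_config <- function(classifier, window_length, preprocess, base_seed,
                       extra = list()) {
  c(list(
    classifier = classifier, window_length = window_length,
    preprocess = unclass(preprocess), base_seed = base_seed,
    package_version = as.character(utils::packageVersion("affectstream"))
  ), extra)
}

classifier_factory <- function(classifier, n_features) {
  force(classifier)
  force(n_features)
  function(seed) {
    args <- c(list(n_features = n_features, seed = seed), classifier)
    do.call(make_classifier, args)
  }
}

#' Immediate-label experiment
#'
#' The offline prequential protocol: preprocess and featurize
#' stimulus-aligned tumbling windows, attach the binarized ratings,
#' then run seeded shuffle-repeats of progressive validation with a
#' fresh classifier per repeat, independently per affect dimension.
#'
#' @param recording An [eeg_recording()].
#' @param labels A `label_stream` covering the recording's stimuli.
#' @param classifier List of [make_classifier()] arguments (at least
#'   `kind`); default: adaptive random forest with five trees.
#' @param window_length Tumbling-window length in seconds.
#' @param dimensions Affect dimensions to model.
#' @param k Number of shuffle-repeats.
#' @param base_seed Base seed for shuffles and classifiers.
#' @param preprocess A [preprocess_config()].
#' @param out_dir Optional directory for run artifacts (metrics JSON and
#'   a reproducibility metadata record).
#' @return List of class `immediate_run`: `features` (labeled feature
#'   table), `results` (per-dimension [shuffled_repeats()]), `config`.
#' @export
run_immediate <- function(recording, labels,
                          classifier = list(kind = "arf", n_trees = 5),
                          window_length = 1,
                          dimensions = c("valence", "arousal"), k = 10,
                          base_seed = 1,
                          preprocess = preprocess_config(),
                          out_dir = NULL) {
  cfg <- window_config(window_length, recording$profile$sampling_rate)
  stimuli <- stimuli_from_labels(labels)
  features <- featurize_recording(recording, cfg, stimuli = stimuli,
                                  preprocess = preprocess)
  features <- assign_labels(features, labels)
  results <- list()
  for (dim in dimensions) {
    sub <- labeled_subset(features, dim)
    fm <- feature_matrix(sub$features)
    results[[dim]] <- shuffled_repeats(
      fm, sub$labels, classifier_factory(classifier, ncol(fm)),
      k = k, base_seed = base_seed
    )
  }
  out <- structure(
    list(
      features = features, results = results,
      config = run_config(classifier, window_length, preprocess, base_seed,
                          list(k = k, protocol = "immediate"))
    ),
    class = "immediate_run"
  )
  if (!is.null(out_dir)) write_run_artifacts(out, out_dir)
  out
}

#' Window-length sweep
#'
#' Repeats the immediate-label experiment for each window length and
#' tabulates the aggregated metrics. The returned table carries an
#' `is_best` flag per dimension marking the length with the highest
#' mean macro F1 (reported, not asserted: on synthetic sessions the
#' optimum need not match any particular real-data finding).
#'
#' @inheritParams run_immediate
#' @param window_lengths Lengths (seconds) to sweep; default 1-5 s.
#' @return Data frame with one row per (length, dimension).
#' @export
run_window_sweep <- function(recording, labels,
                             classifier = list(kind = "arf", n_trees = 5),
                             window_lengths = 1:5,
                             dimensions = c("valence", "arousal"), k = 10,
                             base_seed = 1,
                             preprocess = preprocess_config()) {
  rows <- list()
  for (l in window_lengths) {
    run <- run_immediate(recording, labels, classifier = classifier,
                         window_length = l, dimensions = dimensions,
                         k = k, base_seed = base_seed,
                         preprocess = preprocess)
    for (dim in dimensions) {
      s <- run$results[[dim]]$summary
      rows[[length(rows) + 1L]] <- data.frame(
        window_length = l, dimension = dim,
        n_windows = sum(!is.na(run$features[[paste0("label_", dim)]])),
        mean_macro_f1 = s$mean_macro_f1, sd_macro_f1 = s$sd_macro_f1,
        mean_accuracy = s$mean_accuracy, sd_accuracy = s$sd_accuracy
      )
    }
  }
  out <- do.call(rbind, rows)
  out$is_best <- FALSE
  for (dim in dimensions) {
    sel <- out$dimension == dim
    out$is_best[sel] <- seq_len(sum(sel)) == which.max(out$mean_macro_f1[sel])
  }
  out
}

# Per-window label tuples with an induced fixed arrival lag, used to
# emulate delayed labels on a recording whose true ratings arrived
# immediately: window i's label becomes available `delay_windows`
# windows (i.e. delay_windows * window_length seconds) after the window
# ends.
build_induced_tuples <- function(features, labels, dimension,
                                 delay_windows, window_length) {
  td <- labels[labels$dimension == dimension, , drop = FALSE]
  tol <- 1e-9
  rating <- rep(NA_real_, nrow(features))
  for (j in seq_len(nrow(td))) {
    inside <- features$t_start >= td$t_start[j] - tol &
      features$t_end <= td$t_end[j] + tol
    rating[inside] <- td$rating[j]
  }
  keep <- !is.na(rating)
  data.frame(
    dimension = dimension, rating = rating[keep],
    t_start = features$t_start[keep], t_end = features$t_end[keep],
    arrival = features$t_end[keep] + delay_windows * window_length,
    stringsAsFactors = FALSE
  )
}

#' Delayed-label experiment (live protocol)
#'
#' Two modes:
#' \itemize{
#'   \item Two-part live protocol (`induced_delay_windows = NULL`): the
#'     first `part1_fraction` of the videos is used to train an initial
#'     model on shuffled windows with progressive validation (shuffling
#'     requires the recorded block, hence the part split); the remaining
#'     videos are then streamed through
#'     [delayed_progressive_validate()] resuming from that model, with
#'     each video's rating arriving at the video's end.
#'   \item Induced-delay mode (`induced_delay_windows` set): the whole
#'     session is streamed in time order and every window's true label
#'     arrives a fixed number of windows late (default in the emulated
#'     live study: 86 windows of 1 s, the mean stimulus length).
#' }
#'
#' @inheritParams run_immediate
#' @param dimension Single affect dimension to model.
#' @param classifier Default: adaptive random forest with four trees.
#' @param part1_fraction Fraction of videos in the training part.
#' @param induced_delay_windows Fixed label lag in windows, or `NULL`
#'   for the two-part protocol.
#' @return List of class `delayed_run`: `part1` (training-part
#'   trajectory, `NULL` in induced mode), `delayed` (the delayed
#'   trajectory), `features`, `config`.
#' @export
run_delayed <- function(recording, labels, dimension = "valence",
                        classifier = list(kind = "arf", n_trees = 4),
                        window_length = 1, part1_fraction = 0.5,
                        induced_delay_windows = NULL, base_seed = 1,
                        preprocess = preprocess_config(),
                        out_dir = NULL) {
  cfg <- window_config(window_length, recording$profile$sampling_rate)
  stimuli <- stimuli_from_labels(labels)
  ldim <- labels[labels$dimension == dimension, , drop = FALSE]
  if (nrow(ldim) == 0L) {
    stop(sprintf("no label tuples for dimension '%s'", dimension),
         call. = FALSE)
  }

  if (!is.null(induced_delay_windows)) {
    features <- featurize_recording(recording, cfg, stimuli = stimuli,
                                    preprocess = preprocess)
    tuples <- build_induced_tuples(features, labels, dimension,
                                   induced_delay_windows, window_length)
    clf <- classifier_factory(classifier, 16 * recording$profile$n_channels)(
      base_seed
    )
    delayed <- delayed_progressive_validate(features, tuples, clf,
                                            dimension = dimension)
    part1 <- NULL
  } else {
    n_part1 <- max(1L, floor(nrow(stimuli) * part1_fraction))
    stim1 <- stimuli[seq_len(n_part1), , drop = FALSE]
    stim2 <- stimuli[-seq_len(n_part1), , drop = FALSE]
    if (nrow(stim2) == 0L) {
      stop("no part-2 stimuli left after the split", call. = FALSE)
    }
    f1 <- featurize_recording(recording, cfg, stimuli = stim1,
                              preprocess = preprocess)
    f1 <- assign_labels(f1, labels)
    sub <- labeled_subset(f1, dimension)
    sub$features <- shuffle_labeled_windows(
      cbind(sub$features, .label = sub$labels), seed = base_seed
    )
    clf <- classifier_factory(classifier, 16 * recording$profile$n_channels)(
      base_seed
    )
    part1 <- progressive_validate(
      feature_matrix(sub$features), sub$features$.label, clf
    )
    f2 <- featurize_recording(recording, cfg, stimuli = stim2,
                              preprocess = preprocess)
    tol <- 1e-9
    tuples2 <- ldim[ldim$t_start >= min(stim2$t_start) - tol, , drop = FALSE]
    delayed <- delayed_progressive_validate(f2, tuples2, clf,
                                            dimension = dimension)
    features <- f2
  }
  out <- structure(
    list(
      part1 = part1, delayed = delayed,
      features = if (exists("features", inherits = FALSE)) features else NULL,
      config = run_config(classifier, window_length, preprocess, base_seed,
                          list(dimension = dimension,
                               induced_delay_windows = induced_delay_windows,
                               protocol = "delayed"))
    ),
    class = "delayed_run"
  )
  if (!is.null(out_dir)) write_run_artifacts(out, out_dir)
  out
}

#' Write run artifacts to a directory
#'
#' Emits the predictions log (CSV), a metrics summary (JSON) and a
#' self-contained run-metadata record (JSON: configuration, seeds,
#' package version) sufficient to reproduce the run for deterministic
#' learners.
#'
#' @param run An `immediate_run` or `delayed_run`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_run_artifacts <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  metrics <- if (inherits(run, "immediate_run")) {
    lapply(run$results, function(r) {
      c(r$summary, list(per_repeat = r$per_repeat))
    })
  } else {
    res <- list(delayed = run$delayed$final,
                n_unmatched = run$delayed$n_unmatched)
    if (!is.null(run$part1)) res$part1 <- run$part1$final
    pred_path <- file.path(out_dir, "predictions.csv")
    utils::write.csv(run$delayed$predictions, pred_path, row.names = FALSE)
    paths <- c(paths, pred_path)
    res
  }
  mpath <- file.path(out_dir, "metrics.json")
  jsonlite::write_json(metrics, mpath, auto_unbox = TRUE, digits = 10,
                       dataframe = "rows")
  cpath <- file.path(out_dir, "run_metadata.json")
  jsonlite::write_json(run$config, cpath, auto_unbox = TRUE, digits = 10,
                       force = TRUE)
  invisible(c(paths, mpath, cpath))
}
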