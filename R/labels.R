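# Rating normalization, binary thresholding, interval label assignment.

#' Normalize an affect rating to [0, 1]
#'
#' Supports the two self-report scales used with this pipeline: the
#' continuous Affective Slider (already on the unit scale) and the
#' 9-point Self-Assessment Manikin, which is mapped affinely so that the
#' scale midpoint 5 lands on 0.5 (the class boundary).
#'
#' @param raw Numeric rating(s).
#' @param scale `"unit"` (identity on [0, 1]) or `"sam9"`
#'   (`(raw - 1) / 8` from [1, 9]).
#' @return Rating(s) in [0, 1].
#' @export
#' @examples
#' normalize_rating(5, "sam9") # 0.5
normalize_rating <- function(raw, scale = c("unit", "sam9")) {
  scale <- match.arg(scale)
  raw <- as.numeric(raw)
  if (scale == "unit") {
    if (any(raw < 0 | raw > 1)) {
      stop("unit-scale rating out of [0, 1]", call. = FALSE)
    }
    raw
  } else {
    if (any(raw < 1 | raw > 9)) {
      stop("SAM rating out of [1, 9]", call. = FALSE)
    }
    (raw - 1) / 8
  }
}

#' Binarize a normalized rating into low/high
#'
#' Thresholds a [0, 1] rating at 0.5: ratings at or above the threshold
#' are `"high"`, below are `"low"`. Ties at exactly the threshold go to
#' `"high"` by convention (configurable via `threshold`).
#'
#' @param rating Numeric rating(s) in [0, 1].
#' @param threshold Class boundary (default 0.5).
#' @return Character vector of `"low"` / `"high"`.
#' @export
binarize_rating <- function(rating, threshold = 0.5) {
  rating <- as.numeric(rating)
  if (any(rating < 0 | rating > 1)) {
    stop("rating out of [0, 1]", call. = FALSE)
  }
  ifelse(rating >= threshold, "high", "low")
}

#' Assign interval labels to feature vectors
#'
#' A feature vector receives a tuple's binarized rating for a dimension
#' if and only if its window lies wholly within the tuple's
#' `[t_start, t_end]` interval. Windows matching no tuple stay unlabeled
#' (`NA`); dimensions are independent. Overlapping tuples within one
#' dimension make the ground truth ambiguous and raise an error.
#'
#' @param features A `feature_table` (rows carry `t_start` / `t_end`).
#' @param tuples A `label_stream` data frame, see [label_tuples()].
#' @param threshold Binarization threshold, see [binarize_rating()].
#' @return The feature table with `label_<dimension>` columns added.
#' @export
assign_labels <- function(features, tuples, threshold = 0.5) {
  tol <- 1e-9
  for (dim in c("valence", "arousal")) {
    td <- tuples[tuples$dimension == dim, , drop = FALSE]
    lab <- rep(NA_character_, nrow(features))
    if (nrow(td) > 0L) {
      td <- td[order(td$t_start), , drop = FALSE]
      if (nrow(td) > 1L &&
          any(td$t_start[-1] < td$t_end[-nrow(td)] - tol)) {
        stop(sprintf(
          "overlapping label tuples for dimension '%s': ambiguous ground truth",
          dim
        ), call. = FALSE)
      }
      cls <- binarize_rating(td$rating, threshold)
      for (j in seq_len(nrow(td))) {
        inside <- features$t_start >= td$t_start[j] - tol &
          features$t_end <= td$t_end[j] + tol
        lab[inside] <- cls[j]
      }
    }
    features[[paste0("label_", dim)]] <- lab
  }
  features
}

#' Extract the label vector for one dimension
#' @param features A labeled `feature_table`.
#' @param dimension `"valence"` or `"arousal"`.
#' @param drop_unlabeled Drop rows with no label (default `TRUE`).
#' @return A list with `features` (the possibly subset table) and
#'   `labels` (character vector of `"low"`/`"high"`).
#' @export
labeled_subset <- function(features, dimension, drop_unlabeled = TRUE) {
  col <- paste0("label_", dimension)
  if (!col %in% names(features)) {
    stop(sprintf("no '%s' column; run assign_labels() first", col),
         call. = FALSE)
  }
  lab <- features[[col]]
  if (drop_unlabeled) {
    keep <- !is.na(lab)
    features <- features[keep, , drop = FALSE]
    rownames(features) <- NULL
    lab <- lab[keep]
  }
  list(features = features, labels = lab)
}
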