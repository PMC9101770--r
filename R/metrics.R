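#' Annotation-uncertainty margin mask
#'
#' Manual labelling of activity boundaries carries about 25 ms of
#' uncertainty at 100 Hz, so performance metrics exclude every true change
#' point together with `margin` samples on each side. A change point is the
#' first sample of a new run; the excluded window is truncated at the series
#' boundaries.
#'
#' @param true_labels Binary vector of ground-truth labels.
#' @param margin Samples excluded on each side of a change point
#'   (default 12, i.e. a 25-sample window).
#' @return Logical vector, `TRUE` for samples retained in metric
#'   computations.
#' @export
margin_filter_mask <- function(true_labels, margin = WARM_MARGIN_SAMPLES) {
  n <- length(true_labels)
  mask <- rep(TRUE, n)
  cps <- which(diff(true_labels) != 0) + 1L
  for (cp in cps) {
    mask[max(1L, cp - margin):min(n, cp + margin)] <- FALSE
  }
  mask
}

#' Time-point confusion counts
#'
#' Counts over the masked-in time points, oriented with walking as the
#' positive class: TP = true walking predicted walking, FP = true
#' non-walking predicted walking, FN and TN accordingly.
#'
#' @param true_labels,pred_labels Aligned binary vectors.
#' @param mask Optional logical vector of samples to include (e.g. from
#'   [margin_filter_mask()]); default: all.
#' @return An object of class `confusion_counts`: list with integer
#'   `TP`, `FP`, `FN`, `TN`.
#' @export
confusion <- function(true_labels, pred_labels, mask = NULL) {
  if (length(true_labels) != length(pred_labels)) {
    stop("true and predicted labels must have equal length")
  }
  if (!is.null(mask)) {
    true_labels <- true_labels[mask]
    pred_labels <- pred_labels[mask]
  }
  structure(
    list(TP = sum(true_labels == 1L & pred_labels == 1L),
         FP = sum(true_labels == 0L & pred_labels == 1L),
         FN = sum(true_labels == 1L & pred_labels == 0L),
         TN = sum(true_labels == 0L & pred_labels == 0L)),
    class = "confusion_counts"
  )
}

ratio_or_na <- function(num, den) {
  if (den == 0) NA_real_ else num / den
}

#' Classification metrics from confusion counts
#'
#' Exact ratios: precision `TP/(TP+FP)`, accuracy `(TP+TN)/total`, detection
#' prevalence `(TP+FP)/total` (fraction of time points *predicted* walking)
#' and prevalence `(TP+FN)/total` (fraction *truly* walking). A zero
#' denominator yields `NA` — an undefined metric, never silently 0.
#'
#' @param counts A `confusion_counts` (or anything with `TP`,`FP`,`FN`,`TN`).
#' @return A proportion, or `NA_real_` when undefined.
#' @export
precision <- function(counts) ratio_or_na(counts$TP, counts$TP + counts$FP)

#' @rdname precision
#' @export
accuracy <- function(counts) {
  ratio_or_na(counts$TP + counts$TN, counts$TP + counts$FP + counts$FN + counts$TN)
}

#' @rdname precision
#' @export
detection_prevalence <- function(counts) {
  ratio_or_na(counts$TP + counts$FP, counts$TP + counts$FP + counts$FN + counts$TN)
}

#' @rdname precision
#' @export
prevalence <- function(counts) {
  ratio_or_na(counts$TP + counts$FN, counts$TP + counts$FP + counts$FN + counts$TN)
}

#' Four-class combined segmentation of truth and prediction
#'
#' Each time point is coded from its (true, predicted) pair — (1,1) TP,
#' (0,1) FP, (1,0) FN, (0,0) TN — and maximal runs of constant code become
#' segments. When a margin mask is supplied, masked-out points are removed
#' *before* run-length encoding, so runs separated only by a masked gap are
#' re-joined when their classes match.
#'
#' @inheritParams confusion
#' @param times Optional timestamps, used to report `start_s`/`end_s`.
#' @return Tibble with one row per segment: `class` (TP/FP/FN/TN),
#'   `n_samples`, `start_index`/`end_index` (half-open, positions in the
#'   masked-in subsequence) and, if `times` given, `start_s`/`end_s`.
#' @export
combined_segmentation <- function(true_labels, pred_labels, mask = NULL,
                                  times = NULL) {
  if (length(true_labels) != length(pred_labels)) {
    stop("true and predicted labels must have equal length")
  }
  keep <- if (is.null(mask)) rep(TRUE, length(true_labels)) else mask
  tr <- true_labels[keep]
  pr <- pred_labels[keep]
  cls <- ifelse(tr == 1L, ifelse(pr == 1L, "TP", "FN"),
                ifelse(pr == 1L, "FP", "TN"))
  if (length(cls) == 0) {
    return(tibble::tibble(class = character(0), n_samples = integer(0),
                          start_index = integer(0), end_index = integer(0)))
  }
  r <- rle(cls)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  out <- tibble::tibble(class = r$values, n_samples = r$lengths,
                        start_index = start, end_index = end + 1L)
  if (!is.null(times)) {
    kept_times <- times[keep]
    out$start_s <- kept_times[start]
    out$end_s <- kept_times[end]
  }
  out
}

#' Segment-level confusion counts and metrics
#'
#' Transposes the confusion matrix from time points to activity sessions:
#' each maximal segment of the four-class segmentation counts once,
#' regardless of its duration (set `weight_by_duration = TRUE` to weight
#' each segment by its number of samples instead). Precision and accuracy
#' use the same ratio formulas as their time-point counterparts.
#'
#' @param segments Tibble from [combined_segmentation()].
#' @param weight_by_duration Count samples instead of segments
#'   (default `FALSE`).
#' @return `segment_confusion()`: a `confusion_counts`;
#'   `segment_precision()`/`segment_accuracy()`: a proportion or `NA`.
#' @export
segment_confusion <- function(segments, weight_by_duration = FALSE) {
  if (nrow(segments) == 0) stop("empty segmentation")
  w <- if (weight_by_duration) segments$n_samples else rep(1L, nrow(segments))
  count <- function(cl) sum(w[segments$class == cl])
  structure(list(TP = count("TP"), FP = count("FP"),
                 FN = count("FN"), TN = count("TN")),
            class = "confusion_counts")
}

#' @rdname segment_confusion
#' @export
segment_precision <- function(segments, weight_by_duration = FALSE) {
  precision(segment_confusion(segments, weight_by_duration))
}

#' @rdname segment_confusion
#' @export
segment_accuracy <- function(segments, weight_by_duration = FALSE) {
  accuracy(segment_confusion(segments, weight_by_duration))
}

#' Full metrics report for one or more evaluated trials
#'
#' Computes, per trial and pooled, the time-point metrics (after margin
#' filtering) and the segment-level metrics, in a list ready for JSON
#' serialization.
#'
#' @param evaluated List of per-trial lists with elements `trial_id`,
#'   `true`, `pred`, and optionally `times`.
#' @param margin Margin filter half-width in samples.
#' @return Nested list: `$per_trial`, `$pooled`, `$config`.
#' @export
metrics_report <- function(evaluated, margin = WARM_MARGIN_SAMPLES) {
  one <- function(true, pred, times = NULL) {
    mask <- margin_filter_mask(true, margin)
    cc <- confusion(true, pred, mask)
    seg <- combined_segmentation(true, pred, mask, times)
    list(counts = unclass(cc),
         precision = precision(cc), accuracy = accuracy(cc),
         detection_prevalence = detection_prevalence(cc),
         prevalence = prevalence(cc),
         segment_counts = unclass(segment_confusion(seg)),
         segment_precision = segment_precision(seg),
         segment_accuracy = segment_accuracy(seg))
  }
  per_trial <- lapply(evaluated, function(e) {
    c(list(trial_id = e$trial_id), one(e$true, e$pred, e$times))
  })
  pooled_true <- unlist(lapply(evaluated, `[[`, "true"))
  pooled_pred <- unlist(lapply(evaluated, `[[`, "pred"))
  pooled_mask <- unlist(lapply(evaluated, function(e) margin_filter_mask(e$true, margin)))
  cc <- confusion(pooled_true, pooled_pred, pooled_mask)
  seg_counts <- Reduce(function(a, b) Map(`+`, a, b),
                       lapply(per_trial, `[[`, "segment_counts"))
  pooled <- list(counts = unclass(cc),
                 precision = precision(cc), accuracy = accuracy(cc),
                 detection_prevalence = detection_prevalence(cc),
                 prevalence = prevalence(cc),
                 segment_counts = seg_counts,
                 segment_precision = ratio_or_na(seg_counts$TP, seg_counts$TP + seg_counts$FP),
                 segment_accuracy = ratio_or_na(seg_counts$TP + seg_counts$TN,
                                                Reduce(`+`, seg_counts)))
  list(per_trial = per_trial, pooled = pooled,
       config = list(margin_samples = margin))
}
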