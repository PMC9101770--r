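#' Fit a complete walking activity recognition model
#'
#' Runs the full training pipeline on a set of labelled trials: build the
#' two-dimensional feature space (window `h`), freeze z-score normalization
#' statistics from the pooled training features, tune the classifier over
#' trial-grouped cross-validation with the prevalence-matched
#' one-standard-error strategy, refit it at the selected hyper-parameters on
#' all training trials, and finally tune the a posteriori smoothing on the
#' same folds. The returned model is self-contained: prediction needs
#' nothing but this object.
#'
#' @param trials List of labelled [uqts_trial()] objects (the training
#'   split).
#' @param family Classifier family (see [classifier_spec()]).
#' @param h Sliding-window size in samples (default 50, i.e. 0.5 s at
#'   100 Hz).
#' @param plan A [split_plan()] providing the fold count and seed.
#' @param spec Optional [classifier_spec()] overriding the default grid.
#' @param grids Smoothing grids (default [smoothing_grids()]).
#' @param margin Margin filter half-width in samples.
#' @return An object of class `warm_model` with elements `family`,
#'   `params`, `fit`, `norm_stats`, `h`, `smoothing`, `prevalence`, and the
#'   two tuning audit tables (`classifier_audit`, `smoothing_audit`).
#' @export
warm_fit <- function(trials, family = "decision_tree", h = 50,
                     plan = split_plan(), spec = NULL,
                     grids = smoothing_grids(), margin = WARM_MARGIN_SAMPLES) {
  spec <- spec %||% classifier_spec(family)
  features <- build_features_dataset(trials, h = h)
  norm <- normalize_features(features)
  features <- norm$features
  folds <- make_cv_folds(trial_ids(trials), plan)
  tuned <- tune_classifier(spec, folds, features, margin = margin)
  fit <- fit_classifier(spec, tuned$best_params, features)
  smooth <- tune_smoothing(spec, tuned$best_params, folds, features,
                           grids = grids, margin = margin)
  structure(
    list(family = spec$family, params = tuned$best_params, fit = fit,
         norm_stats = norm$stats, h = h, smoothing = smooth$best,
         prevalence = tuned$actual_prevalence,
         classifier_audit = tuned$records, smoothing_audit = smooth$records),
    class = "warm_model"
  )
}

#' Raw per-time-point predictions for a trial
#'
#' Transforms the trial into the feature space, applies the model's frozen
#' normalization statistics, and classifies each time point independently
#' (no temporal coupling).
#'
#' @param model A `warm_model` from [warm_fit()].
#' @param trial A [uqts_trial()].
#' @return Integer vector of 0/1 predictions of length `P - 1`.
#' @export
predict_raw <- function(model, trial) {
  stopifnot(inherits(model, "warm_model"))
  features <- build_features(trial, h = model$h)
  features <- normalize_features(features, model$norm_stats)$features
  predict_classifier(model$fit, features)
}

#' Predict walking phases for a trial
#'
#' @param object A `warm_model`.
#' @param trial A [uqts_trial()].
#' @param ... Unused.
#' @return Tibble with columns `time`, `lm`, `lsd` (normalized features),
#'   `label` (truth, `NA` if unlabelled), `raw_pred`, `smoothed_pred`,
#'   `trial_id`.
#' @export
predict.warm_model <- function(object, trial, ...) {
  features <- build_features(trial, h = object$h)
  norm <- normalize_features(features, object$norm_stats)$features
  raw <- predict_classifier(object$fit, norm)
  smoothed <- smooth_predictions(raw, norm$time, object$smoothing)
  tibble::tibble(time = norm$time, lm = norm$lm, lsd = norm$lsd,
                 label = norm$label, raw_pred = raw, smoothed_pred = smoothed,
                 trial_id = trial$trial_id)
}

#' @export
print.warm_model <- function(x, ...) {
  cat(sprintf("<warm_model> %s, window h = %d\n", x$family, x$h))
  cat("  params:", paste(names(x$params), unlist(x$params), sep = " = ",
                         collapse = ", "), "\n")
  cat(sprintf("  smoothing: tau = %.2f s, eta = %.2f\n",
              x$smoothing$tau, x$smoothing$eta))
  cat(sprintf("  training walking prevalence (margin-filtered): %.3f\n",
              x$prevalence))
  invisible(x)
}

#' Persist / restore a fitted model
#'
#' The model is written as a single self-describing RDS archive holding the
#' fitted classifier, the frozen normalization statistics, the window size
#' and the smoothing parameters.
#'
#' @param model A `warm_model`.
#' @param path File path.
#' @return `path` (save, invisibly) or the restored `warm_model` (load).
#' @export
warm_save <- function(model, path) {
  stopifnot(inherits(model, "warm_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname warm_save
#' @export
warm_load <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "warm_model"))
  model
}

#' Evaluate a fitted model on held-out trials
#'
#' @param model A `warm_model`.
#' @param trials List of labelled trials.
#' @param margin Margin filter half-width in samples.
#' @param use Which predictions to score: `"smoothed"` or `"raw"`.
#' @return A metrics report (see [metrics_report()]).
#' @export
warm_evaluate <- function(model, trials, margin = WARM_MARGIN_SAMPLES,
                          use = c("smoothed", "raw")) {
  use <- match.arg(use)
  evaluated <- lapply(trials, function(trial) {
    pred <- predict(model, trial)
    list(trial_id = trial$trial_id, true = pred$label,
         pred = if (use == "smoothed") pred$smoothed_pred else pred$raw_pred,
         times = pred$time)
  })
  metrics_report(evaluated, margin = margin)
}
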