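#' Smoothing parameters
#'
#' @param tau Minimal allowed gap between retained change points, seconds.
#' @param eta Walking fraction above which an interval is relabelled
#'   walking, in (0, 1).
#' @return An object of class `smoothing_params`.
#' @export
smoothing_params <- function(tau, eta) {
  if (tau < 0) stop("tau must be non-negative")
  if (eta <= 0 || eta >= 1) stop("eta must be in (0, 1)")
  structure(list(tau = tau, eta = eta), class = "smoothing_params")
}

#' Default smoothing tuning grids
#'
#' `tau` from 0 to 3 s in 0.05 s steps and `eta` from 0.05 to 0.95 in 0.05
#' steps. The 3 s upper bound reflects the experimental design: activity
#' changes are separated by 3-second pauses, so two genuine change points
#' are never closer than 3 s.
#'
#' @return List with numeric vectors `tau` and `eta`.
#' @export
smoothing_grids <- function() {
  list(tau = seq(0, 3, by = 0.05), eta = seq(0.05, 0.95, by = 0.05))
}

#' A posteriori smoothing of raw predictions
#'
#' Exploits the time dependency the per-time-point classifiers ignore:
#' (1) detect change points (a sample whose label differs from its
#' successor's; the change point is indexed at the first sample of the new
#' run); (2) measure the elapsed time between consecutive change points,
#' including the leading and trailing runs; (3) scanning left to right,
#' discard any change point closer than `tau` seconds to the previously
#' *retained* change point (trial boundaries are not change points and never
#' cause a discard); (4) relabel every inter-change-point interval as
#' walking iff its fraction of raw walking predictions exceeds `eta`
#' (strict), else non-walking.
#'
#' With `tau = 0` no change point is discarded and, since every run is then
#' pure, any `eta` in (0, 1) leaves the predictions unchanged.
#'
#' @param raw Binary vector of raw predictions.
#' @param times Timestamps (seconds) aligned with `raw`.
#' @param params A [smoothing_params()] (or a list with `tau` and `eta`).
#' @return Integer vector of smoothed 0/1 predictions, same length as
#'   `raw`.
#' @export
smooth_predictions <- function(raw, times, params) {
  if (length(raw) != length(times)) stop("raw predictions and times must align")
  n <- length(raw)
  if (n == 0) return(integer(0))
  cps <- which(diff(raw) != 0) + 1L # first index of each new run
  kept <- integer(0)
  last_time <- -Inf # no change point retained yet; boundaries never merge
  for (cp in cps) {
    if (times[cp] - last_time < params$tau) next
    kept <- c(kept, cp)
    last_time <- times[cp]
  }
  bounds <- c(1L, kept, n + 1L)
  lens <- diff(bounds)
  cs <- c(0, cumsum(raw))
  frac <- (cs[bounds[-1]] - cs[bounds[-length(bounds)]]) / lens
  rep(as.integer(frac > params$eta), lens)
}

#' Tune the smoothing hyper-parameters over cross-validation folds
#'
#' For each fold the classifier (at its already-tuned hyper-parameters) is
#' fitted on the analysis trials and produces raw predictions for each
#' assessment trial; every `(tau, eta)` grid point is then applied per trial
#' and scored (margin-filtered confusion pooled within the fold). Selection
#' uses the same prevalence-matched one-standard-error strategy as the
#' classifiers, with simplicity order: highest `eta` first, then smallest
#' `tau`.
#'
#' @param spec A [classifier_spec()].
#' @param params Tuned classifier hyper-parameters (one-row tibble).
#' @param folds Folds from [make_cv_folds()].
#' @param features Normalized training feature table.
#' @param grids List with `tau` and `eta` vectors
#'   (default [smoothing_grids()]).
#' @param margin Margin filter half-width in samples.
#' @return List with `best` (a [smoothing_params()]), `records` (audit
#'   table) and `actual_prevalence`.
#' @export
tune_smoothing <- function(spec, params, folds, features,
                           grids = smoothing_grids(),
                           margin = WARM_MARGIN_SAMPLES) {
  mask <- unsplit(lapply(split(features$label, features$trial_id), margin_filter_mask,
                         margin = margin), features$trial_id)
  actual_prev <- mean(features$label[mask])
  grid <- expand.grid(tau = grids$tau, eta = grids$eta)

  # Per fold: raw predictions for each assessment trial, computed once.
  fold_trials <- lapply(folds, function(fold) {
    train <- features[features$trial_id %in% fold$analysis, ]
    fit <- fit_classifier(spec, params, train)
    lapply(fold$assessment, function(id) {
      rows <- features$trial_id == id
      list(raw = predict_classifier(fit, features[rows, ]),
           times = features$time[rows],
           label = features$label[rows],
           mask = mask[rows])
    })
  })

  fold_counts <- lapply(seq_len(nrow(grid)), function(g) {
    sp <- list(tau = grid$tau[g], eta = grid$eta[g])
    lapply(fold_trials, function(trials) {
      cc <- list(TP = 0L, FP = 0L, FN = 0L, TN = 0L)
      for (tr in trials) {
        sm <- smooth_predictions(tr$raw, tr$times, sp)
        cc <- Map(`+`, cc, unclass(confusion(tr$label, sm, tr$mask)))
      }
      structure(cc, class = "confusion_counts")
    })
  })
  records <- fold_metric_records(grid, fold_counts)
  best <- select_warm_params(records, actual_prev,
                             simplicity = c(eta = -1, tau = 1))
  list(best = smoothing_params(records$tau[best], records$eta[best]),
       records = records, actual_prevalence = actual_prev)
}
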