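#' Trial-level data splitting plan
#'
#' Splits always partition *trials*, never time points: all samples of a
#' trial fall on the same side of every split, so no recording leaks across
#' the train/test boundary or across cross-validation folds.
#'
#' @param test_fraction Proportion of trials held out for testing
#'   (default 0.25).
#' @param cv_folds Number of cross-validation folds (default 5).
#' @param seed Integer seed controlling the shuffles.
#' @return An object of class `split_plan`.
#' @export
split_plan <- function(test_fraction = 0.25, cv_folds = 5, seed = 1) {
  if (test_fraction <= 0 || test_fraction >= 1) stop("test_fraction must be in (0, 1)")
  if (cv_folds < 2) stop("need at least 2 folds")
  structure(list(test_fraction = test_fraction, cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed), grouping = "by_trial"),
            class = "split_plan")
}

trial_ids <- function(trials) vapply(trials, `[[`, character(1), "trial_id")

#' Split a dataset into training and test trials
#'
#' @param trials List of [uqts_trial()] objects (at least 4).
#' @param plan A [split_plan()].
#' @return List with `train` and `test` (lists of trials).
#' @export
split_trials <- function(trials, plan = split_plan()) {
  n <- length(trials)
  if (n < 4) stop("need at least 4 trials to split")
  n_test <- max(1L, round(n * plan$test_fraction))
  if (n_test >= n) stop("test fraction leaves no training trials")
  with_seed(plan$seed, {
    test_idx <- sort(sample.int(n, n_test))
    list(train = trials[-test_idx], test = trials[test_idx])
  })
}

#' Trial-grouped cross-validation folds
#'
#' Partitions the training trial identifiers into `cv_folds` assessment
#' sets of as-equal-as-possible size (e.g. 21 trials in 5 folds gives
#' assessment sizes 5,4,4,4,4); the analysis set of each fold is the
#' complement. Every trial appears in exactly one assessment set.
#'
#' @param ids Character vector of training trial identifiers (or a list of
#'   trials).
#' @param plan A [split_plan()].
#' @return List of `cv_folds` lists, each with `analysis` and `assessment`
#'   id vectors.
#' @export
make_cv_folds <- function(ids, plan = split_plan()) {
  if (is.list(ids) && !is.character(ids)) ids <- trial_ids(ids)
  k <- plan$cv_folds
  n <- length(ids)
  if (n < k) stop("fewer trials than folds")
  with_seed(plan$seed + 1L, {
    shuffled <- sample(ids)
    sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
    stopifnot(sum(sizes) == n)
    ends <- cumsum(sizes)
    starts <- ends - sizes + 1L
    lapply(seq_len(k), function(i) {
      assessment <- sort(shuffled[starts[i]:ends[i]])
      list(analysis = sort(setdiff(ids, assessment)), assessment = assessment)
    })
  })
}

fold_se <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(0)
  sd(x) / sqrt(length(x))
}

#' Prevalence-matched one-standard-error hyper-parameter selection
#'
#' Applies, in order: (1) find the combination whose mean detection
#' prevalence is closest to the actual walking prevalence (`target_prev`);
#' (2) keep combinations whose detection prevalence lies within one standard
#' error (of the optimum's) of that optimal detection prevalence; (3) find
#' the highest mean precision among survivors; (4) keep those within one SE
#' of it; (5) the same filter for accuracy; (6) break residual ties by model
#' simplicity (the `simplicity` ordering of the spec: e.g. smallest
#' cost_complexity then smallest tree_depth for trees, highest threshold for
#' logistic). Step-1 ties are broken by grid order.
#'
#' @param records Tibble with one row per grid point, columns
#'   `mean_detection_prevalence`, `se_detection_prevalence`,
#'   `mean_precision`, `se_precision`, `mean_accuracy`, `se_accuracy`, plus
#'   the hyper-parameter columns.
#' @param target_prev Actual walking prevalence the detection prevalence is
#'   matched to.
#' @param simplicity Named numeric vector; names are parameter columns in
#'   tie-break order, values `+1` (prefer smallest) or `-1` (prefer
#'   largest).
#' @return Row index (into `records`) of the selected combination.
#' @export
select_warm_params <- function(records, target_prev, simplicity) {
  stopifnot(nrow(records) >= 1)
  idx <- seq_len(nrow(records))

  # (1)-(2): detection prevalence closest to the actual prevalence, one-SE band
  dp <- records$mean_detection_prevalence
  opt <- idx[which.min(abs(dp - target_prev))]
  band <- records$se_detection_prevalence[opt]
  idx <- idx[abs(dp[idx] - dp[opt]) <= band]

  # (3)-(4): highest precision among survivors, one-SE band
  prec <- ifelse(is.na(records$mean_precision), -Inf, records$mean_precision)
  opt <- idx[which.max(prec[idx])]
  idx <- idx[prec[idx] >= prec[opt] - records$se_precision[opt]]

  # (5): same filter for accuracy
  acc <- ifelse(is.na(records$mean_accuracy), -Inf, records$mean_accuracy)
  opt <- idx[which.max(acc[idx])]
  idx <- idx[acc[idx] >= acc[opt] - records$se_accuracy[opt]]

  # (6): simplicity tie-break in rule order
  if (length(idx) > 1) {
    keys <- lapply(names(simplicity), function(p) simplicity[[p]] * records[[p]][idx])
    idx <- idx[do.call(order, keys)]
  }
  idx[1]
}

fold_metric_records <- function(grid, fold_counts) {
  # fold_counts: list (one per grid row) of lists (one per fold) of
  # confusion_counts; aggregates to mean and SE per metric.
  agg <- lapply(fold_counts, function(per_fold) {
    dp <- vapply(per_fold, detection_prevalence, numeric(1))
    pr <- vapply(per_fold, precision, numeric(1))
    ac <- vapply(per_fold, accuracy, numeric(1))
    c(mean_detection_prevalence = mean(dp, na.rm = TRUE),
      se_detection_prevalence = fold_se(dp),
      mean_precision = if (all(is.na(pr))) NA_real_ else mean(pr, na.rm = TRUE),
      se_precision = fold_se(pr),
      mean_accuracy = mean(ac, na.rm = TRUE),
      se_accuracy = fold_se(ac))
  })
  cbind(tibble::as_tibble(grid), tibble::as_tibble(do.call(rbind, agg)))
}

#' Tune a classifier over trial-grouped cross-validation
#'
#' Evaluates every grid point of the specification on every fold (fit on the
#' analysis trials, predict the assessment trials, count the confusion over
#' margin-filtered time points), aggregates the per-fold detection
#' prevalence, precision and accuracy into means and standard errors, and
#' selects one combination with [select_warm_params()]. The reference
#' prevalence is the actual walking prevalence of the pooled training time
#' points after margin filtering.
#'
#' For the decision tree the full `cost_complexity` grid is obtained by
#' growing one tree per fold and depth at the smallest cost complexity of
#' the grid and pruning it to each larger value (the CART cost-complexity
#' sequence is nested, so this is equivalent to growing at each value).
#'
#' @param spec A [classifier_spec()].
#' @param folds Folds from [make_cv_folds()].
#' @param features Normalized feature table of all training trials (columns
#'   `time`, `lm`, `lsd`, `label`, `trial_id`).
#' @param margin Margin filter half-width in samples.
#' @return List with `best_params` (one-row tibble), `best_index`, `records`
#'   (the full audit table, one row per grid point) and `actual_prevalence`.
#' @export
tune_classifier <- function(spec, folds, features, margin = WARM_MARGIN_SAMPLES) {
  stopifnot(inherits(spec, "classifier_spec"))
  check_features_for_fit(features)
  mask <- unsplit(lapply(split(features$label, features$trial_id), margin_filter_mask,
                         margin = margin), features$trial_id)
  actual_prev <- mean(features$label[mask])
  grid <- spec$grid
  fold_counts <- replicate(nrow(grid), vector("list", length(folds)), simplify = FALSE)
  for (f in seq_along(folds)) {
    a_rows <- features$trial_id %in% folds[[f]]$analysis
    s_rows <- features$trial_id %in% folds[[f]]$assessment
    train <- features[a_rows, ]
    assess <- features[s_rows, ]
    assess_mask <- mask[s_rows]
    if (spec$family == "decision_tree") {
      cp_min <- min(grid$cost_complexity)
      for (depth in unique(grid$tree_depth)) {
        base <- fit_classifier(spec, list(cost_complexity = cp_min, tree_depth = depth),
                               train)
        for (g in which(grid$tree_depth == depth)) {
          fit <- base
          fit$fit <- rpart::prune(base$fit, cp = grid$cost_complexity[g])
          pred <- predict_classifier(fit, assess)
          fold_counts[[g]][[f]] <- confusion(assess$label, pred, assess_mask)
        }
      }
    } else {
      for (g in seq_len(nrow(grid))) {
        fit <- fit_classifier(spec, grid[g, ], train)
        pred <- predict_classifier(fit, assess)
        fold_counts[[g]][[f]] <- confusion(assess$label, pred, assess_mask)
      }
    }
  }
  records <- fold_metric_records(grid, fold_counts)
  best <- select_warm_params(records, actual_prev, spec$simplicity)
  list(best_params = grid[best, ], best_index = best, records = records,
       actual_prevalence = actual_prev)
}
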