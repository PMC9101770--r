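test_that("trial splits partition trials reproducibly", {
  trials <- simulate_dataset(8, 2, short_recipe(), seed = 3)
  plan <- split_plan(test_fraction = 0.25, seed = 5)
  s1 <- split_trials(trials, plan)
  s2 <- split_trials(trials, plan)
  expect_equal(length(s1$train), 6)
  expect_equal(length(s1$test), 2)
  expect_identical(trial_ids(s1$test), trial_ids(s2$test))
  expect_length(intersect(trial_ids(s1$train), trial_ids(s1$test)), 0)
  expect_error(split_trials(trials[1:3], plan), "at least 4")
})

test_that("28 trials split 21/7 and 21 training trials fold into sizes 5,4,4,4,4", {
  ids <- sprintf("trial%02d", 1:28)
  fake <- lapply(ids, function(id) list(trial_id = id))
  plan <- split_plan()
  split <- split_trials(fake, plan)
  expect_equal(length(split$train), 21)
  expect_equal(length(split$test), 7)
  folds <- make_cv_folds(vapply(split$train, `[[`, character(1), "trial_id"), plan)
  sizes <- sort(vapply(folds, function(f) length(f$assessment), integer(1)),
                decreasing = TRUE)
  expect_equal(sizes, c(5L, 4L, 4L, 4L, 4L))
  assessment_union <- sort(unlist(lapply(folds, `[[`, "assessment")))
  expect_equal(assessment_union, sort(vapply(split$train, `[[`, character(1), "trial_id")))
  for (f in folds) expect_length(intersect(f$analysis, f$assessment), 0)
})

test_that("five trials in five folds is leave-one-trial-out", {
  folds <- make_cv_folds(letters[1:5], split_plan(cv_folds = 5))
  expect_true(all(vapply(folds, function(f) length(f$assessment), integer(1)) == 1))
  expect_error(make_cv_folds(letters[1:4], split_plan(cv_folds = 5)), "fewer trials")
})

test_that("a one-point grid is returned unchanged by selection", {
  records <- tibble::tibble(
    threshold = 0.5, mean_detection_prevalence = 0.4,
    se_detection_prevalence = 0.01, mean_precision = 0.9, se_precision = 0.01,
    mean_accuracy = 0.9, se_accuracy = 0.01
  )
  expect_equal(select_warm_params(records, 0.46, c(threshold = -1)), 1)
})

test_that("metric-tied knn candidates resolve to the smallest k", {
  base <- tibble::tibble(
    neighbors = c(3, 5), dist_power = c(2, 2),
    mean_detection_prevalence = c(0.46, 0.46), se_detection_prevalence = c(0.01, 0.01),
    mean_precision = c(0.9, 0.9), se_precision = c(0.01, 0.01),
    mean_accuracy = c(0.9, 0.9), se_accuracy = c(0.01, 0.01)
  )
  expect_equal(select_warm_params(base, 0.46, c(neighbors = 1, dist_power = 1)), 1)
  # order in the table must not matter
  expect_equal(select_warm_params(base[2:1, ], 0.46, c(neighbors = 1, dist_power = 1)), 2)
})

test_that("selection matches the independent rule oracle on randomized audit tables", {
  set.seed(171)
  simplicities <- list(c(alpha = 1, beta = 1), c(alpha = -1), c(beta = 1, alpha = -1))
  for (rep in 1:50) {
    records <- random_audit_table(sample(5:40, 1))
    target <- runif(1, 0.2, 0.8)
    simplicity <- simplicities[[sample.int(3, 1)]]
    expect_equal(select_warm_params(records, target, simplicity),
                 oracle_select(records, target, simplicity))
  }
})

test_that("tuning audits every grid point and never selects outside the grid", {
  set.seed(181)
  trials <- simulate_dataset(6, 2, short_recipe(), seed = 21)
  features <- build_features_dataset(trials, h = 50)
  features <- normalize_features(features)$features
  folds <- make_cv_folds(trial_ids(trials), split_plan(cv_folds = 3, seed = 2))
  grid <- expand.grid(cost_complexity = c(1e-10, 1e-2), tree_depth = c(2, 4))
  spec <- classifier_spec("decision_tree", grid = grid)
  tuned <- tune_classifier(spec, folds, features)
  expect_equal(nrow(tuned$records), nrow(grid))
  expect_true(nrow(merge(as.data.frame(tuned$best_params), grid)) == 1)
  expect_true(all(c("mean_detection_prevalence", "mean_precision", "mean_accuracy",
                    "se_detection_prevalence", "se_precision", "se_accuracy")
                  %in% names(tuned$records)))
  # reference prevalence is the margin-filtered pooled training prevalence
  masks <- lapply(split(seq_len(nrow(features)), features$trial_id),
                  function(rows) margin_filter_mask(features$label[rows]))
  kept <- unlist(Map(function(rows, m) rows[m],
                     split(seq_len(nrow(features)), features$trial_id), masks))
  expect_equal(tuned$actual_prevalence, mean(features$label[kept]))
})

test_that("decision-tree prune fast path equals growing at each cost complexity", {
  set.seed(191)
  trials <- simulate_dataset(4, 2, short_recipe(), seed = 22)
  features <- build_features_dataset(trials, h = 50)
  features <- normalize_features(features)$features
  spec <- classifier_spec("decision_tree")
  for (cp in c(1e-6, 1e-3, 1e-1)) {
    direct <- fit_classifier(spec, list(cost_complexity = cp, tree_depth = 5), features)
    grown <- fit_classifier(spec, list(cost_complexity = 1e-10, tree_depth = 5), features)
    pruned <- rpart::prune(grown$fit, cp = cp)
    probe <- features[sample(nrow(features), 500), ]
    direct_fit <- direct
    pruned_fit <- grown
    pruned_fit$fit <- pruned
    expect_equal(predict_classifier(pruned_fit, probe),
                 predict_classifier(direct_fit, probe), info = paste("cp", cp))
  }
})
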