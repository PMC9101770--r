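test_that("margin mask excludes each change point with 12 samples on each side", {
  expect_true(all(margin_filter_mask(rep(1L, 50))))
  lab <- c(rep(0L, 40), rep(1L, 40))
  mask <- margin_filter_mask(lab)
  expect_equal(which(!mask), (41 - 12):(41 + 12)) # 25 consecutive samples
  # truncation at the series start
  lab2 <- c(rep(0L, 5), rep(1L, 30))
  expect_equal(which(!margin_filter_mask(lab2)), 1:(6 + 12))
})

test_that("confusion counts follow the walking-positive orientation", {
  truth <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  pred <- c(1, 1, 1, 0, 1, 0, 1, 0, 0, 0)
  cc <- confusion(truth, pred)
  expect_equal(unclass(cc), list(TP = 4L, FP = 1L, FN = 1L, TN = 4L))
  perfect <- confusion(truth, truth)
  expect_equal(perfect$FP + perfect$FN, 0L)
  inverted <- confusion(truth, 1 - truth)
  expect_equal(inverted$TP + inverted$TN, 0L)
  expect_error(confusion(truth, pred[-1]), "equal length")
})

test_that("ratio metrics are exact and undefined on zero denominators", {
  cc <- structure(list(TP = 8L, FP = 2L, FN = 1L, TN = 9L), class = "confusion_counts")
  expect_equal(precision(cc), 0.8)
  expect_equal(accuracy(cc), 0.85)
  expect_equal(detection_prevalence(cc), 0.5)
  expect_equal(prevalence(cc), 0.45)
  none <- structure(list(TP = 0L, FP = 0L, FN = 3L, TN = 7L), class = "confusion_counts")
  expect_true(is.na(precision(none))) # undefined, not zero
  expect_equal(accuracy(none), 0.7)
})

test_that("combined segmentation codes (true, pred) pairs into maximal runs", {
  seg <- combined_segmentation(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(seg$class, c("TP", "FN", "TN", "FP"))
  expect_equal(seg$n_samples, rep(1L, 4))
  expect_equal(segment_precision(seg), 0.5) # 1 / (1 + 1)
  expect_equal(segment_accuracy(seg), 0.5) # (1 + 1) / 4
  all_zero <- combined_segmentation(rep(0, 7), rep(0, 7))
  expect_equal(all_zero$class, "TN")
  truth <- rep(c(1, 0, 1), times = c(5, 5, 5))
  same <- combined_segmentation(truth, truth)
  expect_equal(same$class, c("TP", "TN", "TP"))
  expect_equal(segment_precision(same), 1)
})

test_that("segment metrics can diverge from time-point metrics", {
  # one long TP segment against many short FP segments
  truth <- c(rep(1, 30), rep(0, 20))
  pred <- c(rep(1, 30), rep(c(1, 0), times = 10))
  seg <- combined_segmentation(truth, pred)
  tp_prec <- precision(confusion(truth, pred))
  expect_lt(segment_precision(seg), tp_prec)
  # duration weighting recovers the time-point ratio
  expect_equal(segment_precision(seg, weight_by_duration = TRUE), tp_prec)
})

test_that("masked-out gaps re-join surrounding runs of equal class", {
  truth <- c(rep(1, 20), rep(0, 5), rep(1, 20))
  pred <- rep(1, 45)
  mask <- rep(c(TRUE, FALSE, TRUE), times = c(20, 5, 20))
  seg <- combined_segmentation(truth, pred, mask)
  expect_equal(seg$class, "TP") # single re-joined segment
  expect_equal(seg$n_samples, 40L)
})

test_that("counts and segment lengths conserve the number of masked-in points", {
  set.seed(121)
  for (rep in 1:30) {
    n <- sample(20:200, 1)
    truth <- as.integer(runif(n) < 0.5)
    pred <- as.integer(runif(n) < 0.5)
    mask <- margin_filter_mask(truth, margin = 3)
    cc <- confusion(truth, pred, mask)
    expect_equal(cc$TP + cc$FP + cc$FN + cc$TN, sum(mask))
    seg <- combined_segmentation(truth, pred, mask)
    expect_equal(sum(seg$n_samples), sum(mask))
    expect_true(all(diff(seg$start_index) > 0))
    # conservation: prevalence equals detection prevalence whenever FP = FN
    if (cc$FP == cc$FN && sum(mask) > 0) {
      expect_equal(prevalence(cc), detection_prevalence(cc))
    }
  }
})

test_that("metrics reports pool trials and serialize to JSON", {
  trials <- list(
    list(trial_id = "a", true = c(1, 1, 0, 0, 1, 1), pred = c(1, 1, 0, 0, 1, 0),
         times = (1:6) / 100),
    list(trial_id = "b", true = rep(0, 6), pred = rep(0, 6), times = (1:6) / 100)
  )
  report <- metrics_report(trials, margin = 0)
  expect_length(report$per_trial, 2)
  # trial a keeps indices 1,2,4,6 after masking its two change points
  expect_equal(report$pooled$counts$TN, 1L + 6L)
  expect_equal(report$pooled$counts$FN, 1L)
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(report, path, auto_unbox = TRUE)
  expect_true(jsonlite::validate(paste(readLines(path), collapse = "")))
})
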