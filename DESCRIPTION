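Package: warmr
Title: Walking Activity Recognition from Unit Quaternion Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Detects walking phases in hip-rotation recordings from wearable
    motion sensors. A unit-quaternion time series sampled at 100 Hz is turned
    into a two-dimensional feature space via geodesic distances between
    consecutive orientations and causal (left-hand) sliding-window circular
    mean and circular standard deviation. Standard classifiers (CART decision
    tree, radial-basis-function SVM, distance-weighted k-nearest neighbours,
    thresholded logistic regression) are tuned over trial-grouped
    cross-validation with a prevalence-matched one-standard-error selection
    strategy, and per-time-point predictions are smoothed a posteriori by
    merging change points closer than a tuned gap and relabelling intervals by
    their walking fraction. Includes a synthetic annotated gait-trial
    generator, sensor-log CSV input/output, time-point and segment-level
    evaluation metrics with an annotation-uncertainty margin filter, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    kernlab,
    readr,
    rpart,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
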