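#' Classifier specification with default tuning grids
#'
#' The four families compared in the pipeline, each with its default
#' hyper-parameter grid:
#' \describe{
#'   \item{decision_tree}{CART: `cost_complexity` in `10^(-10..-1)`,
#'     `tree_depth` in `1..10`.}
#'   \item{rbf_svm}{Gaussian-kernel soft-margin SVM: `cost` in `2^(-5..5)`,
#'     `rbf_sigma` in `10^(-10..0)`.}
#'   \item{knn}{Distance-weighted k-nearest neighbours: `neighbors` in
#'     `1, 3, ..., 67`, Minkowski `dist_power` in `{1, 2}`.}
#'   \item{logistic}{Unpenalized logit on the two features, hard label =
#'     probability >= `threshold`, `threshold` in `0.05, 0.10, ..., 0.95`.}
#' }
#'
#' @param family One of `"decision_tree"`, `"rbf_svm"`, `"knn"`,
#'   `"logistic"`.
#' @param grid Optional data frame of hyper-parameter combinations
#'   overriding the default grid.
#' @return An object of class `classifier_spec` with elements `family`,
#'   `grid` (tibble, one row per combination) and `simplicity` (ordered
#'   tie-break rules).
#' @export
classifier_spec <- function(family = c("decision_tree", "rbf_svm", "knn", "logistic"),
                            grid = NULL) {
  family <- match.arg(family)
  default <- switch(family,
    decision_tree = expand.grid(cost_complexity = 10^seq(-10, -1),
                                tree_depth = 1:10),
    rbf_svm = expand.grid(cost = 2^seq(-5, 5), rbf_sigma = 10^seq(-10, 0)),
    knn = expand.grid(neighbors = seq(1, 67, by = 2), dist_power = c(1, 2)),
    logistic = expand.grid(threshold = seq(0.05, 0.95, by = 0.05))
  )
  # simplicity rules, applied in order: +1 = prefer smallest, -1 = largest
  simplicity <- switch(family,
    decision_tree = c(cost_complexity = 1, tree_depth = 1),
    rbf_svm = c(cost = 1, rbf_sigma = 1),
    knn = c(neighbors = 1, dist_power = 1),
    logistic = c(threshold = -1)
  )
  grid <- tibble::as_tibble(grid %||% default)
  if (nrow(grid) == 0) stop("empty tuning grid")
  structure(list(family = family, grid = grid, simplicity = simplicity),
            class = "classifier_spec")
}

check_features_for_fit <- function(features) {
  if (!all(c("lm", "lsd", "label") %in% names(features))) {
    stop("features must have columns lm, lsd, label")
  }
  if (anyNA(features$label)) stop("fitting requires labelled features")
  if (length(unique(features$label)) < 2) {
    stop("training labels contain a single class; cannot fit a classifier")
  }
  invisible(TRUE)
}

#' Fit one classifier at fixed hyper-parameters
#'
#' Engines: CART via [rpart::rpart()] (grown and cost-complexity-pruned at
#' `cost_complexity`, depth-capped at `tree_depth`); RBF SVM via
#' [kernlab::ksvm()] with kernel `exp(-sigma * ||u - v||^2)` and box
#' constraint `cost`; k-NN stored training set with Minkowski power
#' `dist_power` and a triangular distance-decay kernel; logistic via
#' [stats::glm()] with hard label = probability >= `threshold`.
#'
#' @param spec A [classifier_spec()].
#' @param params One-row data frame (or named list) of hyper-parameters for
#'   the family.
#' @param features Normalized feature table with `lm`, `lsd`, `label`.
#' @return An object of class `warm_fit`.
#' @export
fit_classifier <- function(spec, params, features) {
  stopifnot(inherits(spec, "classifier_spec"))
  check_features_for_fit(features)
  params <- as.list(params)
  y <- as.integer(features$label)
  fit <- switch(spec$family,
    decision_tree = {
      df <- data.frame(label = factor(y, levels = c(0, 1)),
                       lm = features$lm, lsd = features$lsd)
      rpart::rpart(label ~ lm + lsd, data = df, method = "class",
                   control = rpart::rpart.control(
                     cp = params$cost_complexity,
                     maxdepth = params$tree_depth,
                     xval = 0))
    },
    rbf_svm = {
      X <- cbind(lm = features$lm, lsd = features$lsd)
      kernlab::ksvm(X, factor(y, levels = c(0, 1)), type = "C-svc",
                    kernel = "rbfdot",
                    kpar = list(sigma = params$rbf_sigma),
                    C = params$cost, scaled = FALSE)
    },
    knn = list(X = cbind(features$lm, features$lsd), y = y,
               k = params$neighbors, p = params$dist_power),
    logistic = {
      df <- data.frame(label = y, lm = features$lm, lsd = features$lsd)
      glm(label ~ lm + lsd, data = df, family = binomial())
    }
  )
  structure(list(family = spec$family, params = params, fit = fit),
            class = "warm_fit")
}

# Minkowski-p distances from each row of A (m x 2) to each row of X (n x 2).
minkowski_dist <- function(A, X, p) {
  d1 <- abs(outer(A[, 1], X[, 1], "-"))
  d2 <- abs(outer(A[, 2], X[, 2], "-"))
  if (p == 1) d1 + d2 else if (p == 2) sqrt(d1^2 + d2^2) else (d1^p + d2^p)^(1 / p)
}

predict_knn <- function(model, newX, chunk = 2000L) {
  n <- nrow(newX)
  out <- integer(n)
  k <- model$k
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    D <- minkowski_dist(newX[idx, , drop = FALSE], model$X, model$p)
    out[idx] <- apply(D, 1L, function(d) {
      ord <- order(d)[seq_len(min(k + 1L, length(d)))]
      dk <- d[ord]
      bw <- dk[length(dk)] # (k+1)-th neighbour distance as kernel bandwidth
      w <- if (bw > 0) pmax(1 - dk[seq_len(min(k, length(dk)))] / bw, 0) else NULL
      yk <- model$y[ord[seq_len(min(k, length(ord)))]]
      if (is.null(w) || sum(w) == 0) w <- rep(1, length(yk))
      as.integer(sum(w * yk) / sum(w) > 0.5)
    })
  }
  out
}

#' Predict hard walking labels from a fitted classifier
#'
#' @param object A `warm_fit` from [fit_classifier()].
#' @param features Feature table on the same (normalized) scale as the
#'   training features.
#' @return Integer vector of 0/1 predictions.
#' @export
predict_classifier <- function(object, features) {
  stopifnot(inherits(object, "warm_fit"))
  switch(object$family,
    decision_tree = {
      df <- data.frame(lm = features$lm, lsd = features$lsd)
      as.integer(as.character(predict(object$fit, df, type = "class")))
    },
    rbf_svm = {
      X <- cbind(lm = features$lm, lsd = features$lsd)
      as.integer(as.character(kernlab::predict(object$fit, X)))
    },
    knn = predict_knn(object$fit, cbind(features$lm, features$lsd)),
    logistic = {
      df <- data.frame(lm = features$lm, lsd = features$lsd)
      p <- predict(object$fit, df, type = "response")
      as.integer(p >= object$params$threshold)
    }
  )
}
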