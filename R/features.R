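#' Quaternion finite difference time series
#'
#' Element \eqn{\ell} is the incremental rotation
#' \eqn{q_\ell^{-1} q_{\ell+1}} between consecutive samples, again a unit
#' quaternion. The output is defined on a grid of size \eqn{P - 1}; each
#' differenced value carries the timestamp of the *later* endpoint so the
#' series stays causal for online use.
#'
#' @param trial A [uqts_trial()] with at least 2 time points.
#' @return A `uqts_trial` of length `P - 1` holding the incremental
#'   rotations (labels, if present, aligned to the later endpoints).
#' @export
qfdts <- function(trial) {
  stopifnot(inherits(trial, "uqts_trial"))
  P <- length(trial$times)
  if (P < 2) stop("a finite-difference series needs at least 2 time points")
  Q <- trial$quaternions
  dq <- quat_product(quat_inverse(Q[-P, , drop = FALSE]), Q[-1, , drop = FALSE])
  dq <- dq / quat_norm(dq) # re-normalize products of units
  uqts_trial(trial$times[-1], dq, labels = trial$labels[-1],
             trial_id = trial$trial_id, subject_id = trial$subject_id)
}

#' Quaternion distance time series
#'
#' The real-valued series of geodesic distances (radians) between
#' consecutive quaternions of a trial: the rotation angle the hip swept in
#' each 10 ms step. Length \eqn{P - 1}; values in \eqn{[0, 2\pi]}.
#'
#' @inheritParams qfdts
#' @param fold_double_cover Passed to [quat_geodesic()].
#' @return A list with `times` (later endpoints) and `values` (distances).
#' @export
qdts <- function(trial, fold_double_cover = FALSE) {
  stopifnot(inherits(trial, "uqts_trial"))
  P <- length(trial$times)
  if (P < 2) stop("a distance series needs at least 2 time points")
  Q <- trial$quaternions
  d <- quat_geodesic(Q[-P, , drop = FALSE], Q[-1, , drop = FALSE],
                     fold_double_cover = fold_double_cover)
  list(times = trial$times[-1], values = d)
}

# Left-hand moving sum over windows of `width` samples (current + past),
# truncated at the series start. Direct per-window summation in
# chronological order (no cumulative-sum differencing): long series do not
# accumulate cancellation error and the result matches a streaming buffer
# sum bit for bit.
moving_sum <- function(x, width) {
  x <- as.numeric(x)
  n <- length(x)
  if (width >= n) return(cumsum(x))
  head_part <- cumsum(x[seq_len(width - 1L)])
  body <- rowSums(embed(x, width)[, width:1, drop = FALSE])
  c(head_part, body)
}

#' Sliding-window circular mean of an angle series
#'
#' Element \eqn{\ell} is the circular mean
#' \eqn{atan2(\sum \sin d_m, \sum \cos d_m)} of the angles in the left-hand
#' window \eqn{m = \max(\ell - h, 1), \dots, \ell} (h past samples plus the
#' current one; start-of-series windows are truncated, never padded). With
#' `h = 0` the input is returned unchanged (up to angle wrapping into
#' \eqn{(-\pi, \pi]}).
#'
#' @param x Numeric vector of angles in radians.
#' @param h Window size in samples (non-negative integer).
#' @return Numeric vector, same length as `x`.
#' @export
local_circular_mean <- function(x, h) {
  h <- check_window(h)
  if (h == 0L) return(as.numeric(x)) # windows of one angle: identity, exactly
  atan2(moving_sum(sin(x), h + 1L), moving_sum(cos(x), h + 1L))
}

#' Sliding-window circular standard deviation of an angle series
#'
#' Element \eqn{\ell} is \eqn{\sqrt{-2 \ln \bar R_\ell}}, where
#' \eqn{\bar R_\ell} is the mean resultant length of the angles in the same
#' left-hand window as [local_circular_mean()] (divisor = the actual,
#' possibly truncated, window length). With `h = 0` every window holds one
#' angle, \eqn{\bar R = 1}, and the series is identically zero.
#'
#' Antipodal windows have \eqn{\bar R = 0} and an infinite circular SD; a
#' mean resultant length below `1e-12` is numerically indistinguishable
#' from zero, so such values are replaced by `cap` (default: the largest
#' finite value in the series) with a warning. Single-angle windows (the
#' first element of any series) have \eqn{\bar R = 1} and SD 0 exactly.
#'
#' @inheritParams local_circular_mean
#' @param cap Replacement for infinite values; `NULL` means the maximum
#'   finite value of the series (0 if none).
#' @return Non-negative numeric vector, same length as `x`.
#' @export
local_circular_sd <- function(x, h, cap = NULL) {
  h <- check_window(h)
  if (h == 0L) return(numeric(length(x))) # R-bar = 1 in every window, exactly
  len <- pmin(seq_along(x), h + 1L)
  rbar <- sqrt(moving_sum(cos(x), h + 1L)^2 + moving_sum(sin(x), h + 1L)^2) / len
  out <- sqrt(-2 * log(pmin(rbar, 1)))
  out[len == 1L] <- 0 # one angle: R-bar = 1 by definition
  inf <- !is.finite(out) | (rbar < 1e-12 & len > 1L)
  if (any(inf)) {
    out[inf] <- Inf
    cap <- cap %||% if (all(inf)) 0 else max(out[!inf])
    warning(sprintf("%d antipodal window(s) with zero resultant length; circular SD capped at %.6g",
                    sum(inf), cap))
    out[inf] <- cap
  }
  out
}

check_window <- function(h) {
  if (length(h) != 1L || !is.finite(h) || h < 0 || h != floor(h)) {
    stop("window size h must be a single non-negative integer")
  }
  as.integer(h)
}

#' Build the two-dimensional feature table of a trial
#'
#' Chains [qdts()], [local_circular_mean()] and [local_circular_sd()]: the
#' local-mean distance (`lm`) and the local-SD distance (`lsd`) are the only
#' two predictors the classifiers ever see. The first raw time point is
#' consumed by differencing, so labels (when present) are aligned to the
#' remaining timestamps.
#'
#' @inheritParams qdts
#' @param h Window size in samples; the default 50 spans 0.5 s at 100 Hz.
#' @param lsd_cap Passed to [local_circular_sd()] as `cap`.
#' @return A tibble with columns `time`, `lm`, `lsd`, `label` (`NA` if the
#'   trial is unlabelled) and `trial_id`.
#' @export
build_features <- function(trial, h = 50, fold_double_cover = FALSE, lsd_cap = NULL) {
  d <- qdts(trial, fold_double_cover = fold_double_cover)
  lm <- local_circular_mean(d$values, h)
  lsd <- local_circular_sd(lm, h, cap = lsd_cap)
  tibble::tibble(
    time = d$times,
    lm = lm,
    lsd = lsd,
    label = if (is.null(trial$labels)) NA_integer_ else trial$labels[-1],
    trial_id = trial$trial_id
  )
}

#' Build and row-bind feature tables for a list of trials
#'
#' @param trials List of [uqts_trial()] objects.
#' @inheritParams build_features
#' @return A single tibble (see [build_features()]).
#' @export
build_features_dataset <- function(trials, h = 50, fold_double_cover = FALSE) {
  do.call(rbind, lapply(trials, build_features, h = h,
                        fold_double_cover = fold_double_cover))
}

#' Normalize the feature space
#'
#' Z-scores the `lm` and `lsd` columns. When `stats` is `NULL` the centering
#' and scaling constants are estimated from the table (the training split);
#' pass the returned stats to normalize validation/test tables with the
#' training-derived constants, never re-estimated.
#'
#' @param features Feature table from [build_features()].
#' @param stats Optional `warm_norm_stats` from a previous call.
#' @return List with `features` (normalized table) and `stats`
#'   (a `warm_norm_stats`: `lm_center`, `lm_scale`, `lsd_center`, `lsd_scale`).
#' @export
normalize_features <- function(features, stats = NULL) {
  if (is.null(stats)) {
    stats <- structure(
      list(lm_center = mean(features$lm), lm_scale = sd(features$lm),
           lsd_center = mean(features$lsd), lsd_scale = sd(features$lsd)),
      class = "warm_norm_stats"
    )
  }
  if (!all(is.finite(c(stats$lm_scale, stats$lsd_scale))) ||
      stats$lm_scale <= 0 || stats$lsd_scale <= 0) {
    stop("cannot normalize a constant feature column (zero scale)")
  }
  features$lm <- (features$lm - stats$lm_center) / stats$lm_scale
  features$lsd <- (features$lsd - stats$lsd_center) / stats$lsd_scale
  list(features = features, stats = stats)
}
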