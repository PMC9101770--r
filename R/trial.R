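#' Unit-quaternion time series trial
#'
#' Container for one recording: timestamps on a uniform grid (default step
#' 10 ms, i.e. 100 Hz), one unit quaternion per time point, and optional
#' per-time-point binary activity labels (1 = walking).
#'
#' @param times Numeric vector of seconds, strictly increasing with a
#'   constant step (within `1e-6` s).
#' @param quaternions `P x 4` matrix of unit quaternions, columns
#'   `(w, x, y, z)`; unit norm enforced within `1e-6`.
#' @param labels Optional integer vector of length `P` with values in
#'   `{0, 1}`.
#' @param trial_id,subject_id Identifier strings.
#' @return An object of class `uqts_trial`: a list with elements `times`,
#'   `quaternions`, `labels`, `trial_id`, `subject_id`.
#' @export
uqts_trial <- function(times, quaternions, labels = NULL,
                       trial_id = "trial", subject_id = "subject") {
  quaternions <- as_quat_matrix(quaternions)
  times <- as.numeric(times)
  P <- length(times)
  if (nrow(quaternions) != P) stop("times and quaternions must have equal length")
  if (P >= 2) {
    steps <- diff(times)
    if (any(steps <= 0)) stop("times must be strictly increasing")
    # uniform grid within 1e-6 s; gaps from rejected samples are tolerated
    # as integer multiples of the base step
    dt <- min(steps)
    if (max(abs(steps - round(steps / dt) * dt)) > 1e-6) {
      stop("times must lie on a uniform grid (constant step within 1e-6 s)")
    }
  }
  check_unit(quaternions, tol = 1e-6, what = "trial quaternion")
  if (!is.null(labels)) {
    if (length(labels) != P) stop("labels must have one value per time point")
    labels <- as.integer(labels)
    if (!all(labels %in% c(0L, 1L))) stop("labels must be binary (0/1)")
  }
  structure(
    list(times = times, quaternions = quaternions, labels = labels,
         trial_id = as.character(trial_id), subject_id = as.character(subject_id)),
    class = "uqts_trial"
  )
}

#' @export
print.uqts_trial <- function(x, ...) {
  P <- length(x$times)
  dt <- if (P >= 2) mean(diff(x$times)) else NA_real_
  cat(sprintf("<uqts_trial> %s (subject %s): %d samples", x$trial_id, x$subject_id, P))
  if (!is.na(dt)) cat(sprintf(" @ %.0f Hz, %.1f s", 1 / dt, diff(range(x$times))))
  if (!is.null(x$labels)) {
    cat(sprintf(", walking prevalence %.3f", mean(x$labels)))
  } else {
    cat(", unlabelled")
  }
  cat("\n")
  invisible(x)
}

#' @export
length.uqts_trial <- function(x) length(x$times)
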