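#' Streaming (sample-by-sample) feature computation
#'
#' Creates a stateful feature stream equivalent to [build_features()] but fed
#' one quaternion at a time, as a sensor chip would: only current and past
#' samples are used and memory is bounded by the window size. The first
#' pushed sample yields no output (differencing needs two points); every
#' subsequent push emits one `(lm, lsd)` pair whose start-of-series windows
#' are truncated to the available history, exactly as in batch mode.
#'
#' @param h Window size in samples (as in [build_features()]).
#' @param fold_double_cover Passed to [quat_geodesic()].
#' @return An object of class `warm_stream`: a list of functions
#'   `push(q, t)` (returns `NULL` or a list with `time`, `lm`, `lsd`) and
#'   `reset()`.
#' @examples
#' s <- warm_stream(h = 2)
#' s$push(quat(1, 0, 0, 0), 0.00) # NULL: no differenced value yet
#' s$push(quat(cos(0.01), 0, 0, sin(0.01)), 0.01)
#' @export
warm_stream <- function(h, fold_double_cover = FALSE) {
  h <- check_window(h)
  prev_q <- NULL
  prev_t <- -Inf
  d_buf <- numeric(0) # last <= h+1 geodesic distances
  lm_buf <- numeric(0) # last <= h+1 local circular means
  push <- function(q, t) {
    if (t <= prev_t) stop("out-of-order timestamp in stream")
    qm <- as_quat_matrix(q)
    first <- is.null(prev_q)
    d <- if (!first) quat_geodesic(prev_q, qm, fold_double_cover = fold_double_cover)
    prev_q <<- qm
    prev_t <<- t
    if (first) return(invisible(NULL))
    d_buf <<- c(if (length(d_buf) > h) d_buf[-1] else d_buf, d)
    lm <- if (h == 0L) d else atan2(sum(sin(d_buf)), sum(cos(d_buf)))
    lm_buf <<- c(if (length(lm_buf) > h) lm_buf[-1] else lm_buf, lm)
    lsd <- if (h == 0L || length(lm_buf) == 1L) {
      0
    } else {
      rbar <- sqrt(sum(cos(lm_buf))^2 + sum(sin(lm_buf))^2) / length(lm_buf)
      if (rbar < 1e-12) Inf else sqrt(-2 * log(min(rbar, 1)))
    }
    list(time = t, lm = lm, lsd = lsd)
  }
  reset <- function() {
    prev_q <<- NULL
    prev_t <<- -Inf
    d_buf <<- numeric(0)
    lm_buf <<- numeric(0)
    invisible(NULL)
  }
  structure(list(push = push, reset = reset, h = h), class = "warm_stream")
}
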