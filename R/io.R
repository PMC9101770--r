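#' Sensor-log CSV dialect
#'
#' Vendors disagree on column naming, quaternion component order and time
#' units, so readers/writers take an explicit dialect. The default matches
#' the package's own export: a column of elapsed seconds followed by the
#' quaternion components in `(w, x, y, z)` order.
#'
#' @param time_column Name of the timestamp column.
#' @param quaternion_columns Character vector of the four component columns,
#'   in `(w, x, y, z)` order.
#' @param time_unit One of `"seconds"`, `"milliseconds"`, `"epoch_ms"`.
#' @param delimiter Field delimiter.
#' @return An object of class `sensor_dialect`.
#' @export
sensor_dialect <- function(time_column = "elapsed_s",
                           quaternion_columns = c("w", "x", "y", "z"),
                           time_unit = c("seconds", "milliseconds", "epoch_ms"),
                           delimiter = ",") {
  time_unit <- match.arg(time_unit)
  if (length(quaternion_columns) != 4L || anyDuplicated(quaternion_columns)) {
    stop("quaternion_columns must be 4 distinct names in (w, x, y, z) order")
  }
  structure(list(time_column = time_column,
                 quaternion_columns = quaternion_columns,
                 time_unit = time_unit, delimiter = delimiter),
            class = "sensor_dialect")
}

# fread parses doubles with correct rounding (readr's fast parser can be
# off by one ulp, which would break exact round-trips of timestamps).
read_table_quiet <- function(path, delimiter = ",") {
  tibble::as_tibble(data.table::fread(path, sep = delimiter, data.table = FALSE,
                                      showProgress = FALSE))
}

#' Read a sensor-log CSV into a trial
#'
#' Timestamps are converted to seconds from the first sample. Rows with any
#' non-finite component are rejected; quaternions whose norm deviates from 1
#' by at most `1e-3` are renormalized, rows deviating further are rejected.
#' Rejections are reported (with row numbers) and reading fails if more than
#' 1% of rows are dropped.
#'
#' @param path CSV file path.
#' @param dialect A [sensor_dialect()].
#' @param trial_id,subject_id Identifiers for the returned trial.
#' @return A [uqts_trial()] (unlabelled; see [apply_labels()]).
#' @export
read_uqts_csv <- function(path, dialect = sensor_dialect(),
                          trial_id = NULL, subject_id = "subject") {
  df <- read_table_quiet(path, dialect$delimiter)
  needed <- c(dialect$time_column, dialect$quaternion_columns)
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop("missing column(s) in ", path, ": ", paste(missing_cols, collapse = ", "))
  }
  times <- as.numeric(df[[dialect$time_column]])
  Q <- as.matrix(df[dialect$quaternion_columns])
  colnames(Q) <- c("w", "x", "y", "z")
  if (dialect$time_unit %in% c("milliseconds", "epoch_ms")) times <- times / 1000
  norms <- sqrt(rowSums(Q^2))
  bad <- !is.finite(times) | !is.finite(norms) | abs(norms - 1) > 1e-3
  if (any(bad)) {
    rows <- which(bad)
    message(sprintf("%s: rejected %d row(s): %s", basename(path), length(rows),
                    paste(head(rows, 10), collapse = ", ")))
    if (mean(bad) > 0.01) {
      stop(sprintf("more than 1%% of rows rejected in %s (%d of %d)",
                   path, sum(bad), nrow(df)))
    }
    times <- times[!bad]
    Q <- Q[!bad, , drop = FALSE]
    norms <- norms[!bad]
  }
  if (is.unsorted(times, strictly = TRUE)) stop("non-monotone timestamps in ", path)
  times <- times - times[1]
  Q <- Q / norms
  trial_id <- trial_id %||% sub("\\.[^.]*$", "", basename(path))
  uqts_trial(times, Q, trial_id = trial_id, subject_id = subject_id)
}

#' Write a trial as a sensor-log CSV
#'
#' @param trial A [uqts_trial()].
#' @inheritParams read_uqts_csv
#' @return `path`, invisibly.
#' @export
write_uqts_csv <- function(trial, path, dialect = sensor_dialect()) {
  df <- tibble::as_tibble(stats::setNames(
    c(list(trial$times), as.list(as.data.frame(trial$quaternions))),
    c(dialect$time_column, dialect$quaternion_columns)
  ))
  if (dialect$time_unit %in% c("milliseconds", "epoch_ms")) {
    df[[dialect$time_column]] <- df[[dialect$time_column]] * 1000
  }
  readr::write_delim(df, path, delim = dialect$delimiter)
  invisible(path)
}

#' Read labelled activity intervals
#'
#' Expects columns `start_s`, `end_s`, `walking` (0/1) and optionally
#' `activity`. Intervals are half-open `[start_s, end_s)` in seconds and
#' must not overlap.
#'
#' @param path CSV file path.
#' @return Tibble of intervals.
#' @export
read_labels_csv <- function(path) {
  df <- read_table_quiet(path)
  needed <- c("start_s", "end_s", "walking")
  if (!all(needed %in% names(df))) {
    stop("labels file needs columns: ", paste(needed, collapse = ", "))
  }
  check_intervals(df)
  tibble::as_tibble(df)
}

#' Write labelled activity intervals
#'
#' @param intervals Tibble with `start_s`, `end_s`, (`activity`,) `walking`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_labels_csv <- function(intervals, path) {
  readr::write_delim(tibble::as_tibble(intervals), path, delim = ",")
  invisible(path)
}

check_intervals <- function(intervals) {
  if (nrow(intervals) < 2) return(invisible(TRUE))
  o <- order(intervals$start_s)
  if (any(intervals$end_s[o][-nrow(intervals)] > intervals$start_s[o][-1] + 1e-9)) {
    stop("overlapping annotation intervals")
  }
  invisible(TRUE)
}

#' Assign per-sample labels from annotation intervals
#'
#' A sample at time `t` is labelled by the interval with
#' `start_s <= t < end_s` (half-open: a sample exactly on a boundary belongs
#' to the starting interval); samples outside all intervals get label 0.
#'
#' @param trial A [uqts_trial()].
#' @param intervals Tibble as from [read_labels_csv()].
#' @return The trial with `labels` filled in.
#' @export
apply_labels <- function(trial, intervals) {
  check_intervals(intervals)
  labels <- integer(length(trial$times))
  for (i in seq_len(nrow(intervals))) {
    inside <- trial$times >= intervals$start_s[i] & trial$times < intervals$end_s[i]
    labels[inside] <- as.integer(intervals$walking[i])
  }
  trial$labels <- labels
  trial
}

#' Write / read a prediction table
#'
#' Deterministic column order `time,lm,lsd,label,raw_pred,smoothed_pred`;
#' full double precision, so tables round-trip exactly.
#'
#' @param predictions Tibble with the columns above (plus `trial_id`).
#' @param path CSV path.
#' @return `path` (writer, invisibly) or the tibble (reader).
#' @export
write_predictions_csv <- function(predictions, path) {
  cols <- c("time", "lm", "lsd", "label", "raw_pred", "smoothed_pred", "trial_id")
  cols <- intersect(cols, names(predictions))
  readr::write_delim(predictions[cols], path, delim = ",")
  invisible(path)
}

#' @rdname write_predictions_csv
#' @export
read_predictions_csv <- function(path) {
  read_table_quiet(path)
}

#' Write / read a segment table
#'
#' Columns `start_s,end_s,class,n_samples`; an empty segment set writes a
#' header-only file.
#'
#' @param segments Tibble with the columns above.
#' @param path CSV path.
#' @return `path` (writer, invisibly) or the tibble (reader).
#' @export
write_segments_csv <- function(segments, path) {
  cols <- c("start_s", "end_s", "class", "n_samples")
  cols <- intersect(cols, names(segments))
  readr::write_delim(segments[cols], path, delim = ",")
  invisible(path)
}

#' @rdname write_segments_csv
#' @export
read_segments_csv <- function(path) {
  read_table_quiet(path)
}
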