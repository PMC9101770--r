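#' Recipe for a synthetic annotated gait trial
#'
#' Describes one simulated walking-path trial: an ordered activity schedule
#' (walking bouts of several kinds, sit/stand holds, and pauses), a sample
#' rate, and the three components of the orientation signal — a slow drift,
#' a periodic hip oscillation at the cadence frequency during walking, and
#' small-angle jitter. The default schedule lasts 90 s, inserts a 3 s pause
#' at every change of activity, and implies a walking prevalence of about
#' 0.46, mirroring a typical instrumented walking-path protocol.
#'
#' @param sample_rate Sampling frequency in Hz (default 100).
#' @param schedule Data frame with columns `activity` (one of
#'   `r paste(ACTIVITY_KINDS, collapse = ", ")`) and `duration` (seconds);
#'   default [default_activity_schedule()].
#' @param pause_duration Pause length in seconds used by the default
#'   schedule builder (default 3).
#' @param cadence Step frequency during walking, steps/second (default 1.8).
#' @param sway_amplitude Amplitude of the periodic hip oscillation, radians
#'   (default 0.15).
#' @param jitter_sd SD of per-sample small-angle orientation noise, radians
#'   (default 0.002).
#' @param drift_rate Slow orientation drift, radians/second (default 0.01).
#' @param seed Integer seed making the trial reproducible.
#' @return An object of class `trial_recipe`.
#' @export
trial_recipe <- function(sample_rate = 100,
                         schedule = default_activity_schedule(pause_duration),
                         pause_duration = 3,
                         cadence = 1.8,
                         sway_amplitude = 0.15,
                         jitter_sd = 0.002,
                         drift_rate = 0.01,
                         seed = NULL) {
  schedule <- tibble::as_tibble(schedule)
  if (nrow(schedule) == 0) stop("activity schedule must not be empty")
  if (!all(c("activity", "duration") %in% names(schedule))) {
    stop("schedule needs columns 'activity' and 'duration'")
  }
  if (!all(schedule$activity %in% ACTIVITY_KINDS)) {
    stop("unknown activity kind(s): ",
         paste(setdiff(schedule$activity, ACTIVITY_KINDS), collapse = ", "))
  }
  if (any(schedule$duration <= 0)) stop("activity durations must be positive")
  if (sample_rate <= 0) stop("sample_rate must be positive")
  if (sway_amplitude < 0 || jitter_sd < 0) stop("amplitudes must be non-negative")
  structure(
    list(sample_rate = sample_rate, schedule = schedule,
         pause_duration = pause_duration, cadence = cadence,
         sway_amplitude = sway_amplitude, jitter_sd = jitter_sd,
         drift_rate = drift_rate, seed = seed),
    class = "trial_recipe"
  )
}

#' Default 90-second walking-path schedule
#'
#' Alternates walking bouts (straight, curved, stairs) with sit/stand holds,
#' separated by pauses at every activity change. Total duration 90 s with
#' `pause_duration = 3`; walking prevalence 41/90 = 0.456.
#'
#' @inheritParams trial_recipe
#' @return Tibble with columns `activity` and `duration`.
#' @export
default_activity_schedule <- function(pause_duration = 3) {
  acts <- c("straight_walk", "sit_stand", "curved_walk", "sit_stand",
            "stairs", "sit_stand", "straight_walk")
  durs <- c(12, 10, 10, 10, 8, 11, 11)
  activity <- character(0)
  duration <- numeric(0)
  for (i in seq_along(acts)) {
    if (i > 1) {
      activity <- c(activity, "pause")
      duration <- c(duration, pause_duration)
    }
    activity <- c(activity, acts[i])
    duration <- c(duration, durs[i])
  }
  tibble::tibble(activity = activity, duration = duration)
}

#' Named difficulty presets for the simulator
#'
#' `"easy"` is the default recipe; `"hard"` multiplies the jitter SD by 5
#' and halves the sway amplitude, shrinking the separation between walking
#' and non-walking features.
#'
#' @param preset `"easy"` or `"hard"`.
#' @param ... Overrides passed on to [trial_recipe()].
#' @return A `trial_recipe`.
#' @export
recipe_preset <- function(preset = c("easy", "hard"), ...) {
  preset <- match.arg(preset)
  recipe <- trial_recipe(...)
  if (preset == "hard") {
    recipe$jitter_sd <- recipe$jitter_sd * 5
    recipe$sway_amplitude <- recipe$sway_amplitude * 0.5
  }
  recipe
}

# Uniformly distributed random unit axes, n x 3.
random_axes <- function(n) {
  v <- matrix(rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

#' Simulate one annotated unit-quaternion trial
#'
#' The orientation at each sample is the composition (Hamilton product) of:
#' a slow drift rotation about a fixed random axis at `drift_rate` rad/s; a
#' sinusoidal oscillation of amplitude `sway_amplitude` at the cadence
#' frequency during walking activities (about the x body axis for straight
#' walking and the y axis for curved walking and stairs, so the walking
#' kinds are not identical in feature space); and an independent per-sample
#' small random rotation of angle `N(0, jitter_sd)` about a random axis.
#' Jitter is composed as a rotation, not added to components, so samples
#' stay on the unit sphere by construction. Pauses and sit/stand holds get
#' drift + jitter only. A sample is labelled walking (1) iff its activity is
#' a walking kind. Deterministic given `recipe$seed`.
#'
#' @param recipe A [trial_recipe()].
#' @param trial_id,subject_id Identifiers stored in the trial.
#' @return A [uqts_trial()] with labels, plus a `$intervals` attribute-like
#'   element recording the ground-truth activity intervals (tibble with
#'   `start_s`, `end_s`, `activity`, `walking`; half-open `[start, end)`).
#' @export
simulate_trial <- function(recipe, trial_id = "trial01", subject_id = "S1") {
  stopifnot(inherits(recipe, "trial_recipe"))
  with_seed(recipe$seed, {
    dt <- 1 / recipe$sample_rate
    total <- sum(recipe$schedule$duration)
    P <- round(total * recipe$sample_rate)
    times <- (seq_len(P) - 1) * dt
    ends <- cumsum(recipe$schedule$duration)
    starts <- c(0, head(ends, -1))
    # half-open [start, end): a boundary sample belongs to the starting activity
    seg <- findInterval(times, starts)
    activity <- recipe$schedule$activity[seg]
    labels <- as.integer(activity %in% WALKING_KINDS)

    drift_axis <- random_axes(1)[1, ]
    q_drift <- axis_angle_quat(drift_axis, recipe$drift_rate * times)

    local_t <- times - starts[seg]
    osc_angle <- ifelse(labels == 1L,
                        recipe$sway_amplitude * sin(2 * pi * recipe$cadence * local_t),
                        0)
    osc_x <- axis_angle_quat(c(1, 0, 0), osc_angle)
    osc_y <- axis_angle_quat(c(0, 1, 0), osc_angle)
    use_y <- activity %in% c("curved_walk", "stairs")
    q_osc <- osc_x
    q_osc[use_y, ] <- osc_y[use_y, ]

    jit_axes <- random_axes(P)
    jit_angle <- rnorm(P, 0, recipe$jitter_sd)
    q_jit <- cbind(cos(jit_angle / 2), sin(jit_angle / 2) * jit_axes)

    Q <- quat_product(quat_product(q_drift, q_osc), q_jit)
    Q <- Q / quat_norm(Q)

    trial <- uqts_trial(times, Q, labels = labels,
                        trial_id = trial_id, subject_id = subject_id)
    trial$intervals <- tibble::tibble(
      start_s = starts, end_s = ends,
      activity = recipe$schedule$activity,
      walking = as.integer(recipe$schedule$activity %in% WALKING_KINDS)
    )
    trial
  })
}

#' Simulate a dataset of annotated trials
#'
#' Trials are assigned to subjects round-robin; each subject gets a fixed
#' random perturbation (within +/-10%) of the recipe's cadence and sway
#' amplitude, emulating between-subject gait variability. Per-trial RNG
#' streams are derived from `seed`, so the dataset is reproducible.
#'
#' @param n_trials,n_subjects Counts with `n_trials >= n_subjects >= 1`.
#' @param recipe Template [trial_recipe()].
#' @param seed Integer seed (defaults to the recipe's seed, or 1).
#' @return List of [uqts_trial()] objects.
#' @export
simulate_dataset <- function(n_trials = 28, n_subjects = 3,
                             recipe = trial_recipe(), seed = NULL) {
  if (n_subjects < 1 || n_trials < n_subjects) {
    stop("need n_trials >= n_subjects >= 1")
  }
  seed <- seed %||% recipe$seed %||% 1L
  with_seed(seed, {
    cad_f <- runif(n_subjects, 0.9, 1.1)
    amp_f <- runif(n_subjects, 0.9, 1.1)
    trial_seeds <- sample.int(.Machine$integer.max - 1L, n_trials)
    lapply(seq_len(n_trials), function(i) {
      s <- ((i - 1L) %% n_subjects) + 1L
      r <- recipe
      r$cadence <- recipe$cadence * cad_f[s]
      r$sway_amplitude <- recipe$sway_amplitude * amp_f[s]
      r$seed <- trial_seeds[i]
      simulate_trial(r, trial_id = sprintf("trial%02d", i),
                     subject_id = sprintf("S%d", s))
    })
  })
}
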