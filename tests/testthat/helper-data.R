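# Small fixtures built in code.

# A short (~22 s) schedule exercising all activity kinds, for fast tests.
short_schedule <- function() {
  tibble::tibble(
    activity = c("straight_walk", "pause", "sit_stand", "pause",
                 "curved_walk", "pause", "stairs"),
    duration = c(4, 3, 3, 3, 4, 3, 2)
  )
}

short_recipe <- function(seed = 1, ...) {
  trial_recipe(schedule = short_schedule(), seed = seed, ...)
}

# Synthetic randomized audit table for exercising the selection rules.
random_audit_table <- function(n, params = list(alpha = NULL, beta = NULL)) {
  tibble::tibble(
    alpha = round(runif(n), 3),
    beta = sample(1:5, n, replace = TRUE),
    mean_detection_prevalence = runif(n, 0.2, 0.8),
    se_detection_prevalence = runif(n, 0.005, 0.1),
    mean_precision = runif(n, 0.4, 1),
    se_precision = runif(n, 0.005, 0.1),
    mean_accuracy = runif(n, 0.4, 1),
    se_accuracy = runif(n, 0.005, 0.1)
  )
}
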