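constant_trial <- function(P = 20, q = quat(1, 0, 0, 0)) {
  uqts_trial((seq_len(P) - 1) / 100, matrix(q, P, 4, byrow = TRUE))
}

rotating_trial <- function(P, theta_step) {
  angles <- (seq_len(P) - 1) * theta_step
  uqts_trial((seq_len(P) - 1) / 100,
             cbind(cos(angles / 2), 0, 0, sin(angles / 2)))
}

test_that("qfdts returns incremental rotations on a grid of size P - 1", {
  trial <- constant_trial(10)
  dq <- qfdts(trial)
  expect_equal(length(dq$times), 9)
  expect_equal(unname(dq$quaternions), matrix(c(1, 0, 0, 0), 9, 4, byrow = TRUE))
  set.seed(71)
  Q <- random_unit_quats(2)
  two <- uqts_trial(c(0, 0.01), Q)
  dq2 <- qfdts(two)
  expect_equal(unname(dq2$quaternions[1, ]),
               unname(quat_product(quat_inverse(Q[1, ]), Q[2, ])),
               tolerance = 1e-12)
  expect_equal(dq2$times, 0.01) # timestamp of the later endpoint
  expect_error(qfdts(constant_trial(1)), "at least 2")
})

test_that("qdts is zero for constant trials and constant for uniform rotation", {
  expect_equal(qdts(constant_trial(15))$values, rep(0, 14))
  theta <- 0.02
  d <- qdts(rotating_trial(50, theta))
  expect_equal(d$values, rep(theta, 49), tolerance = 1e-12)
  expect_equal(length(d$times), 49)
})

test_that("qdts matches elementwise inverse-product-arccos composition on random trials", {
  set.seed(81)
  Q <- random_unit_quats(40)
  # random quaternions are not a uniform-grid trial; build one artificially
  trial <- uqts_trial((1:40) / 100, Q)
  d <- qdts(trial)$values
  manual <- vapply(1:39, function(l) {
    2 * acos(max(-1, min(1, quat_product(quat_inverse(Q[l, ]), Q[l + 1, ])[["w"]])))
  }, numeric(1))
  expect_equal(d, manual, tolerance = 1e-12)
})

test_that("local circular mean: h = 0 identity, constants, and the two-angle window", {
  x <- runif(30, 0, pi)
  expect_identical(local_circular_mean(x, 0), x)
  expect_equal(local_circular_mean(rep(1.2, 25), 7), rep(1.2, 25), tolerance = 1e-12)
  # window {0, pi/2}: atan2(1, 1) = pi/4
  expect_equal(local_circular_mean(c(0, pi / 2), 1)[2], pi / 4, tolerance = 1e-12)
  expect_error(local_circular_mean(x, -1), "non-negative")
})

test_that("local circular sd: h = 0 zeros, constants, and the two-angle window", {
  x <- runif(30, 0, pi)
  expect_identical(local_circular_sd(x, 0), rep(0, 30))
  expect_equal(local_circular_sd(rep(0.7, 25), 5), rep(0, 25), tolerance = 1e-7)
  # window {0, pi/2}: R-bar = |(1 + i)| / 2 = sqrt(2)/2
  expect_equal(local_circular_sd(c(0, pi / 2), 1)[2],
               sqrt(-2 * log(sqrt(2) / 2)), tolerance = 1e-12)
})

test_that("windowed circular statistics match the brute-force oracle", {
  set.seed(91)
  for (rep in 1:25) {
    n <- sample(5:60, 1)
    h <- sample(0:12, 1)
    x <- runif(n, 0, 2) # tight enough that wrapping never differs
    expect_lt(max(abs(local_circular_mean(x, h) - oracle_circ_mean(x, h))), 1e-12)
    lm <- local_circular_mean(x, h)
    expect_lt(max(abs(local_circular_sd(lm, h) - oracle_circ_sd(lm, h))), 1e-12)
  }
})

test_that("antipodal windows cap the infinite circular SD with a warning", {
  x <- c(0, pi, 0.3, 0.31, 0.32)
  expect_warning(out <- local_circular_sd(x, 1), "antipodal")
  expect_true(all(is.finite(out)))
  expect_equal(out[2], max(out[-2])) # capped at the max finite value
})

test_that("circular mean of a tight cluster behaves like an arithmetic mean", {
  set.seed(101)
  x <- runif(100, -1.2, 1.2) # all within (-pi/2, pi/2)
  lm <- local_circular_mean(x, 9)
  for (l in seq_along(x)) {
    win <- x[max(1, l - 9):l]
    expect_gte(lm[l], min(win) - 1e-9)
    expect_lte(lm[l], max(win) + 1e-9)
  }
})

test_that("build_features chains the transforms and aligns labels", {
  recipe <- short_recipe(seed = 5)
  trial <- simulate_trial(recipe)
  f <- build_features(trial, h = 50)
  expect_equal(nrow(f), length(trial$times) - 1)
  expect_equal(f$time, trial$times[-1])
  expect_equal(f$label, trial$labels[-1])
  expect_true(all(is.finite(f$lm)) && all(is.finite(f$lsd)))
  # constant trial: both feature columns exactly zero
  fc <- build_features(constant_trial(120), h = 50)
  expect_equal(fc$lm, rep(0, 119))
  expect_equal(fc$lsd, rep(0, 119))
})

test_that("feature normalization freezes training statistics", {
  recipe <- short_recipe(seed = 6)
  f <- build_features(simulate_trial(recipe))
  norm <- normalize_features(f)
  expect_equal(mean(norm$features$lm), 0, tolerance = 1e-9)
  expect_equal(sd(norm$features$lm), 1, tolerance = 1e-9)
  expect_equal(sd(norm$features$lsd), 1, tolerance = 1e-9)
  # applying training stats to new data must not re-estimate
  f2 <- build_features(simulate_trial(short_recipe(seed = 7)))
  norm2 <- normalize_features(f2, norm$stats)
  expect_identical(norm2$stats, norm$stats)
  expect_gt(abs(mean(norm2$features$lm)), 1e-6)
  # constant column is a hard error
  fc <- f
  fc$lsd <- 1
  expect_error(normalize_features(fc), "zero scale|constant")
})
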