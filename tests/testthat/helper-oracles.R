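# Independent oracles used to cross-check the implementation. These follow
# different computational routes than the package code on purpose.

random_unit_quats <- function(n) {
  m <- matrix(rnorm(4 * n), ncol = 4)
  m / sqrt(rowSums(m^2))
}

# Rotation-matrix image of a unit quaternion (w, x, y, z).
quat_to_rotmat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# Shepperd-style recovery of a unit quaternion from a rotation matrix.
rotmat_to_quat <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(diag(R))
    j <- (i %% 3) + 1
    k <- (j %% 3) + 1
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1] <- s / 4
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[k + 1] <- (R[k, i] + R[i, k]) / s
  }
  q / sqrt(sum(q^2))
}

# Hamilton product through the rotation-matrix representation (defined up
# to quaternion sign; align the sign with the reference before comparing).
oracle_product <- function(a, b) {
  q <- rotmat_to_quat(quat_to_rotmat(a) %*% quat_to_rotmat(b))
  q
}

align_sign <- function(q, reference) if (sum(q * reference) < 0) -q else q

# Brute-force left-window circular statistics through complex arithmetic.
oracle_circ_mean <- function(x, h) {
  vapply(seq_along(x), function(l) {
    Arg(mean(exp(1i * x[max(1, l - h):l])))
  }, numeric(1))
}

oracle_circ_sd <- function(x, h) {
  vapply(seq_along(x), function(l) {
    win <- x[max(1, l - h):l]
    if (length(win) == 1) return(0) # SD of a single angle is zero
    sqrt(-2 * log(min(Mod(mean(exp(1i * win))), 1)))
  }, numeric(1))
}

# Independent re-implementation of the six-step selection strategy using
# data-frame subsetting (the package version works on index vectors).
oracle_select <- function(records, target_prev, simplicity) {
  df <- as.data.frame(records)
  df$.row <- seq_len(nrow(df))
  gap <- abs(df$mean_detection_prevalence - target_prev)
  best_dp <- df[which.min(gap), ]
  df <- df[abs(df$mean_detection_prevalence - best_dp$mean_detection_prevalence) <=
             best_dp$se_detection_prevalence, ]
  p <- df$mean_precision
  p[is.na(p)] <- -Inf
  best_p <- df[which.max(p), ]
  thr <- (if (is.na(best_p$mean_precision)) -Inf else best_p$mean_precision) -
    best_p$se_precision
  df <- df[p >= thr, ]
  a <- df$mean_accuracy
  a[is.na(a)] <- -Inf
  best_a <- df[which.max(a), ]
  thr <- (if (is.na(best_a$mean_accuracy)) -Inf else best_a$mean_accuracy) -
    best_a$se_accuracy
  df <- df[a >= thr, ]
  df <- df[do.call(order, lapply(names(simplicity), function(p) simplicity[[p]] * df[[p]])), ]
  df$.row[1]
}
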