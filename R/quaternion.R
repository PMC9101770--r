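#' Quaternion algebra for rotation time series
#'
#' A quaternion \eqn{q = w + xi + yj + zk} is stored as a numeric vector
#' `c(w, x, y, z)` (scalar part first); a set of quaternions as an `n x 4`
#' matrix with one quaternion per row. All functions accept either form and
#' recycle a single quaternion against a matrix. The component order is
#' always `(w, x, y, z)`: sensor exports disagree on ordering, so every
#' reader/writer in the package states it explicitly.
#'
#' @param w,x,y,z Real components: scalar part `w`, vector part `(x, y, z)`.
#' @return `quat()` returns a named numeric vector of length 4.
#' @examples
#' q <- quat(cos(pi / 8), 0, 0, sin(pi / 8)) # 45 degrees about z
#' quat_norm(q)
#' quat_geodesic(quat(1, 0, 0, 0), q)
#' @export
quat <- function(w, x, y, z) {
  q <- c(w = w, x = x, y = y, z = z)
  stopifnot(is.numeric(q), length(q) == 4L)
  q
}

as_quat_matrix <- function(q) {
  if (is.matrix(q)) {
    if (ncol(q) != 4L) stop("quaternion matrix must have 4 columns (w, x, y, z)")
    q
  } else {
    if (length(q) != 4L) stop("a quaternion has 4 components (w, x, y, z)")
    matrix(as.numeric(q), nrow = 1L)
  }
}

#' Euclidean 4-norm of quaternions
#'
#' @param q A quaternion (length-4 vector) or an `n x 4` matrix of quaternions.
#' @return Numeric vector of norms, one per quaternion.
#' @export
quat_norm <- function(q) {
  m <- as_quat_matrix(q)
  sqrt(rowSums(m^2))
}

#' Quaternion conjugate
#'
#' @inheritParams quat_norm
#' @return Conjugate quaternion(s) `(w, -x, -y, -z)`, same shape as the input.
#' @export
quat_conjugate <- function(q) {
  m <- as_quat_matrix(q)
  m[, 2:4] <- -m[, 2:4]
  if (is.matrix(q)) m else quat(m[1, 1], m[1, 2], m[1, 3], m[1, 4])
}

#' Quaternion inverse
#'
#' For a unit quaternion the inverse equals the conjugate.
#'
#' @inheritParams quat_norm
#' @return Inverse quaternion(s), same shape as the input.
#' @export
quat_inverse <- function(q) {
  m <- as_quat_matrix(q)
  n2 <- rowSums(m^2)
  if (any(n2 == 0)) stop("the zero quaternion has no inverse")
  out <- cbind(m[, 1], -m[, 2], -m[, 3], -m[, 4]) / n2
  if (is.matrix(q)) out else quat(out[1, 1], out[1, 2], out[1, 3], out[1, 4])
}

#' Hamilton product of quaternions
#'
#' Non-commutative quaternion multiplication defined by
#' \eqn{i^2 = j^2 = k^2 = ijk = -1}. Vectorized row-wise; a single
#' quaternion is recycled against a matrix argument.
#'
#' @param a,b Quaternions (length-4 vectors or `n x 4` matrices).
#' @return The product `ab`, as a matrix if either input was a matrix.
#' @export
quat_product <- function(a, b) {
  am <- as_quat_matrix(a)
  bm <- as_quat_matrix(b)
  if (nrow(am) != nrow(bm)) {
    if (nrow(am) == 1L) am <- am[rep(1L, nrow(bm)), , drop = FALSE]
    else if (nrow(bm) == 1L) bm <- bm[rep(1L, nrow(am)), , drop = FALSE]
    else stop("incompatible numbers of quaternions")
  }
  w <- am[, 1] * bm[, 1] - am[, 2] * bm[, 2] - am[, 3] * bm[, 3] - am[, 4] * bm[, 4]
  x <- am[, 1] * bm[, 2] + am[, 2] * bm[, 1] + am[, 3] * bm[, 4] - am[, 4] * bm[, 3]
  y <- am[, 1] * bm[, 3] - am[, 2] * bm[, 4] + am[, 3] * bm[, 1] + am[, 4] * bm[, 2]
  z <- am[, 1] * bm[, 4] + am[, 2] * bm[, 3] - am[, 3] * bm[, 2] + am[, 4] * bm[, 1]
  out <- cbind(w, x, y, z)
  colnames(out) <- c("w", "x", "y", "z")
  if (is.matrix(a) || is.matrix(b)) out else quat(w, x, y, z)
}

check_unit <- function(q, tol = 1e-6, what = "quaternion") {
  dev <- abs(quat_norm(q) - 1)
  if (any(dev > tol)) {
    stop(sprintf("%s must be unit-norm (max |norm - 1| = %.3g > %.1g)",
                 what, max(dev), tol))
  }
  invisible(TRUE)
}

#' Geodesic distance between unit quaternions
#'
#' The angle (radians) of the relative rotation: \eqn{2 \arccos Re(a^{-1}b)},
#' which for unit quaternions reduces to twice the arccosine of their dot
#' product. The real part is clipped to \eqn{[-1, 1]} to absorb floating-point
#' drift, so the result lies in \eqn{[0, 2\pi]} and is exactly 0 when `a = b`.
#' The real part is not folded by absolute value: this is the distance on the
#' unit sphere of quaternions, where a rotation and its double-cover antipode
#' are 2\eqn{\pi} apart. Set `fold_double_cover = TRUE` to obtain the
#' rotation-group distance \eqn{\min(d, 2\pi - d)} in \eqn{[0, \pi]} instead.
#'
#' @param a,b Unit quaternions (length-4 vectors or `n x 4` matrices);
#'   validated to be unit-norm within `1e-6`.
#' @param fold_double_cover Logical; fold antipodal pairs onto the rotation
#'   group (default `FALSE`).
#' @return Numeric vector of distances in radians.
#' @export
quat_geodesic <- function(a, b, fold_double_cover = FALSE) {
  am <- as_quat_matrix(a)
  bm <- as_quat_matrix(b)
  check_unit(am, what = "geodesic distance input")
  check_unit(bm, what = "geodesic distance input")
  if (nrow(am) != nrow(bm)) {
    if (nrow(am) == 1L) am <- am[rep(1L, nrow(bm)), , drop = FALSE]
    else if (nrow(bm) == 1L) bm <- bm[rep(1L, nrow(am)), , drop = FALSE]
    else stop("incompatible numbers of quaternions")
  }
  # Re(a^{-1} b) = <a, b> for unit a.
  d <- 2 * acos(clip(rowSums(am * bm), -1, 1))
  # identical quaternions are exactly distance 0 (their dot product may
  # round to just under 1, which acos would turn into ~3e-8)
  d[rowSums((am - bm)^2) == 0] <- 0
  if (fold_double_cover) d <- pmin(d, 2 * pi - d)
  d
}

# Unit quaternion for a rotation of `angle` radians about `axis` (length-3,
# need not be normalized). Vectorized over `angle` for a fixed axis.
axis_angle_quat <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  half <- angle / 2
  cbind(w = cos(half), x = sin(half) * axis[1],
        y = sin(half) * axis[2], z = sin(half) * axis[3])
}
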