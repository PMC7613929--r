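#' Rigid-body transforms
#'
#' A `rigid_transform` is a proper rotation `R` (3x3, det = +1) plus a
#' translation `t` (3-vector, Angstrom), acting on column vectors as
#' `y = R x + t`.  All quaternary-geometry analyses in protofil are built
#' on compositions and decompositions of these transforms.
#'
#' @param rotation 3x3 proper orthogonal matrix.
#' @param translation numeric 3-vector (Angstrom).
#' @param tol orthogonality/determinant tolerance.
#' @return An object of class `rigid_transform` with elements `rotation`
#'   and `translation`.
#' @examples
#' t1 <- rigid_transform(diag(3), c(1, 0, 0))
#' rt_apply(t1, matrix(0, 1, 3))
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0), tol = 1e-9) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(identical(dim(rotation), c(3L, 3L)), length(translation) == 3L)
  if (!all(is.finite(rotation)) || !all(is.finite(translation)))
    stop("rigid_transform: non-finite entries")
  dev <- max(abs(crossprod(rotation) - diag(3)))
  if (dev > sqrt(tol))
    stop("rigid_transform: rotation is not orthogonal (deviation ",
         format(dev), ")")
  if (det(rotation) < 0)
    stop("rigid_transform: improper rotation (determinant < 0); ",
         "reflections are not rigid-body motions")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform\n")
  m <- cbind(x$rotation, x$translation)
  dimnames(m) <- list(NULL, c("r1", "r2", "r3", "t"))
  print(round(m, 6))
  invisible(x)
}

is_rigid_transform <- function(x) inherits(x, "rigid_transform")

#' Identity transform
#' @return The identity `rigid_transform`.
#' @export
rt_identity <- function() rigid_transform(diag(3), c(0, 0, 0))

#' Apply a rigid transform to coordinates
#'
#' @param t a [rigid_transform()].
#' @param x an n x 3 coordinate matrix (rows are points) or a 3-vector.
#' @return Transformed coordinates, same shape as `x`.
#' @export
rt_apply <- function(t, x) {
  stopifnot(is_rigid_transform(t))
  if (is.null(dim(x))) {
    stopifnot(length(x) == 3L)
    return(drop(t$rotation %*% x) + t$translation)
  }
  stopifnot(ncol(x) == 3L)
  sweep(x %*% t(t$rotation), 2L, t$translation, "+")
}

#' Compose rigid transforms
#'
#' `rt_compose(a, b)` returns the transform equivalent to applying `b`
#' first, then `a` (function composition a o b).
#' @param a,b [rigid_transform()] objects.
#' @export
rt_compose <- function(a, b) {
  stopifnot(is_rigid_transform(a), is_rigid_transform(b))
  rigid_transform(a$rotation %*% b$rotation,
                  drop(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param t a [rigid_transform()].
#' @export
rt_inverse <- function(t) {
  stopifnot(is_rigid_transform(t))
  rigid_transform(t(t$rotation), drop(-t(t$rotation) %*% t$translation))
}

#' Integer power of a rigid transform
#' @param t a [rigid_transform()].
#' @param k integer power (>= 0).
#' @export
rt_power <- function(t, k) {
  stopifnot(is_rigid_transform(t), k >= 0, k == round(k))
  out <- rt_identity()
  for (i in seq_len(k)) out <- rt_compose(t, out)
  out
}

#' Rotation matrix from axis and angle
#'
#' Right-handed rotation by `angle_deg` about the (not necessarily unit)
#' vector `axis`, via Rodrigues' formula.
#' @param axis 3-vector, rotation axis.
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  axis <- as.numeric(axis)
  n <- sqrt(sum(axis^2))
  if (n == 0) stop("rotation_about_axis: zero axis")
  u <- axis / n
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Construct a screw transform from its elements
#'
#' Rotation by `twist_deg` about the axis through `point` along
#' `direction`, plus a translation of `rise` Angstrom along the axis.
#' @param direction axis direction (3-vector, need not be unit length).
#' @param point a point on the axis (3-vector, Angstrom).
#' @param twist_deg rotation angle about the axis, degrees.
#' @param rise translation along the axis, Angstrom.
#' @export
rt_from_screw <- function(direction, point = c(0, 0, 0), twist_deg = 0,
                          rise = 0) {
  d <- as.numeric(direction)
  d <- d / sqrt(sum(d^2))
  R <- rotation_about_axis(d, twist_deg)
  p <- as.numeric(point)
  tr <- rise * d + p - drop(R %*% p)
  rigid_transform(R, tr)
}

#' Rotation angle of a rotation matrix
#' @param R 3x3 rotation matrix.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
rotation_angle <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- min(1, max(-1, ct))
  acos(ct) * 180 / pi
}

# Axis (unit vector) of a rotation matrix; angle_deg as returned by
# rotation_angle().  For angle ~ 0 the axis is undefined and (0,0,1) is
# returned.  For angle ~ 180 the axis sign is arbitrary and fixed to the
# first nonzero component positive.
rotation_axis <- function(R, angle_deg = rotation_angle(R)) {
  a <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  na <- sqrt(sum(a^2))
  if (na > 1e-8) return(a / na)
  if (angle_deg < 90) return(c(0, 0, 1))
  # angle near 180: columns of (R + I)/2 are proportional to u u^T
  B <- (R + diag(3)) / 2
  j <- which.max(diag(B))
  u <- B[, j] / sqrt(B[j, j])
  k <- which(abs(u) > 1e-8)[1]
  if (u[k] < 0) u <- -u
  u / sqrt(sum(u^2))
}

# random proper rotation, uniform (Haar) via QR of Gaussian matrix
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
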