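#' Screw-axis decomposition of a rigid transform
#'
#' Every proper rigid transform equals a rotation (the *twist*) about a
#' unique axis combined with a translation (the *rise*) along that axis
#' (Chasles' theorem).  Repeated application of the transform places
#' copies of an object on a helix around the screw axis, which is how a
#' single inter-subunit operator encodes the helical symmetry of a
#' protein filament.
#'
#' Sign convention: the axis direction is chosen so that the rise is
#' non-negative; when the rise is (numerically) zero the direction is
#' chosen so that the twist is non-negative.  This removes the
#' `(d, theta) <-> (-d, -theta)` ambiguity deterministically.  The twist
#' is reported in `(-180, 180]` degrees.
#'
#' @param t a [rigid_transform()].
#' @param twist_tol twists below this (degrees) are treated as zero and
#'   the transform flagged as a pure translation.
#' @param rise_tol rises below this (Angstrom) are treated as zero.
#' @return An object of class `screw_axis`: list with `direction` (unit
#'   3-vector), `point` (a point on the axis, the one closest to the
#'   origin), `twist_deg`, `rise` (Angstrom) and `pure_translation`
#'   (logical).
#' @seealso [screw_recompose()], [helical_parameters()]
#' @examples
#' s <- screw_decompose(rt_from_screw(c(0, 0, 1), c(100, 0, 0), 27.7, 48))
#' s$twist_deg; s$rise
#' @export
screw_decompose <- function(t, twist_tol = 1e-6, rise_tol = 1e-6) {
  stopifnot(is_rigid_transform(t))
  R <- t$rotation
  v <- t$translation
  ang <- rotation_angle(R)

  if (ang < twist_tol) {
    nv <- sqrt(sum(v^2))
    d <- if (nv > rise_tol) v / nv else c(0, 0, 1)
    return(new_screw_axis(d, c(0, 0, 0), 0,
                          if (nv > rise_tol) nv else 0,
                          pure_translation = TRUE))
  }

  d <- rotation_axis(R, ang)
  rise <- sum(v * d)
  # fix the sign convention before solving for the axis point
  if (abs(rise) > rise_tol) {
    if (rise < 0) { d <- -d; rise <- -rise; ang <- -ang }
  } else {
    rise <- 0
    # twist >= 0 convention; ang is already >= 0 for the returned axis
  }
  twist <- normalize_angle(ang)

  # axis point: solve (I - R) p = v_perp restricted to the plane
  # perpendicular to the axis, where (I - R) is invertible for twist != 0
  vperp <- v - sum(v * d) * d
  basis <- orthonormal_complement(d)
  M <- crossprod(basis, (diag(3) - R) %*% basis)  # 2x2
  rhs <- crossprod(basis, vperp)
  p2 <- solve(M, rhs)
  p <- drop(basis %*% p2)
  # report the axis point closest to the origin (p is already _|_ d)
  p <- p - sum(p * d) * d

  new_screw_axis(d, p, twist, rise, pure_translation = FALSE)
}

new_screw_axis <- function(direction, point, twist_deg, rise,
                           pure_translation) {
  structure(list(direction = as.numeric(direction),
                 point = as.numeric(point),
                 twist_deg = as.numeric(twist_deg),
                 rise = as.numeric(rise),
                 pure_translation = isTRUE(pure_translation)),
            class = "screw_axis")
}

#' @export
print.screw_axis <- function(x, ...) {
  cat(sprintf(
    "screw_axis: twist %.4f deg, rise %.4f A%s\n  direction (%.4f, %.4f, %.4f)  point (%.2f, %.2f, %.2f)\n",
    x$twist_deg, x$rise,
    if (x$pure_translation) " [pure translation]" else "",
    x$direction[1], x$direction[2], x$direction[3],
    x$point[1], x$point[2], x$point[3]))
  invisible(x)
}

#' Rebuild the rigid transform encoded by a screw axis
#' @param s a `screw_axis` as returned by [screw_decompose()].
#' @return The equivalent [rigid_transform()].
#' @export
screw_recompose <- function(s) {
  stopifnot(inherits(s, "screw_axis"))
  rt_from_screw(s$direction, s$point, s$twist_deg, s$rise)
}

# map an angle in degrees to (-180, 180]
normalize_angle <- function(a) {
  a <- a %% 360
  ifelse(a > 180, a - 360, a)
}

# two unit vectors spanning the plane perpendicular to unit vector d
orthonormal_complement <- function(d) {
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * d) * d
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  cbind(e1, e2)
}
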