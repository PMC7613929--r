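#' Helical parameters of an inter-subunit transform
#'
#' Converts the operator between consecutive subunits into filament
#' helical parameters: twist (degrees), rise (Angstrom), helical radius
#' (perpendicular distance of the reference subunit centroid from the
#' screw axis), subunits per turn (360/|twist|) and handedness (right
#' when twist and rise share a sign under the protofil convention, i.e.
#' positive twist, since the rise is normalised to be non-negative).
#'
#' @param t a [rigid_transform()] carrying subunit k onto subunit k+1,
#'   e.g. from [transform_between_subunits()].
#' @param reference_centroid 3-vector, centroid of the reference subunit.
#' @return A `helical_params`: `twist_deg`, `rise`, `helical_radius`,
#'   `subunits_per_turn` (NA when twist is zero), `handedness`
#'   (`"left"`, `"right"`, `"none"`), `axis` (the `screw_axis`),
#'   `degenerate` (TRUE for pure translations / identity).
#' @export
helical_parameters <- function(t, reference_centroid) {
  ax <- screw_decompose(t)
  v <- as.numeric(reference_centroid) - ax$point
  vperp <- v - sum(v * ax$direction) * ax$direction
  radius <- sqrt(sum(vperp^2))
  twist <- ax$twist_deg
  degenerate <- ax$pure_translation
  spt <- if (abs(twist) > 0) 360 / abs(twist) else NA_real_
  hand <- if (degenerate || abs(twist) < 1e-6 || abs(ax$rise) < 1e-6) {
    "none"
  } else if (twist > 0) "right" else "left"
  structure(list(twist_deg = twist, rise = ax$rise,
                 helical_radius = radius, subunits_per_turn = spt,
                 handedness = hand, axis = ax, degenerate = degenerate),
            class = "helical_params")
}

#' @export
print.helical_params <- function(x, ...) {
  cat(sprintf(
    "helical_params: twist %.3f deg, rise %.3f A, radius %.1f A, %s subunits/turn, %s-handed%s\n",
    x$twist_deg, x$rise, x$helical_radius,
    if (is.na(x$subunits_per_turn)) "NA"
    else sprintf("%.2f", x$subunits_per_turn),
    x$handedness, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Helical parameters from a multi-subunit filament
#'
#' Estimates per-subunit twist, rise and helical radius from a filament
#' of three or more subunits by screw-decomposing the *composed*
#' transform from the first to the k-th subunit and dividing by k.  For
#' noisy coordinates this is markedly more accurate than a single
#' neighbour-pair estimate: the screw-axis direction error of a small
#' rotation is amplified into the rise and radius in proportion to the
#' helical radius, and composing over k subunits reduces it about
#' k-fold.  k is capped so the composed twist stays below 175 degrees
#' (no wrap-around).
#'
#' @param s a [fil_structure()] whose chains are consecutive subunits.
#' @param chains subunit chains in filament order (default: all polymer
#'   chains in structure order).
#' @param elety atom names used for superposition (default main chain).
#' @return A `helical_params` (see [helical_parameters()]) with an
#'   extra field `k` (the number of steps composed).
#' @export
helical_parameters_filament <- function(s, chains = NULL,
                                        elety = c("N", "CA", "C")) {
  if (is.null(chains)) chains <- polymer_chains(s)
  if (length(chains) < 2)
    stop("helical_parameters_filament: need >= 2 subunits")
  tr1 <- transform_between_subunits(s, chains[1], chains[2],
                                    elety = elety)
  rough <- abs(screw_decompose(tr1$transform)$twist_deg)
  k <- if (rough < 1e-6) length(chains) - 1L else
    max(1L, min(length(chains) - 1L, floor(175 / rough)))
  trk <- transform_between_subunits(s, chains[1], chains[1 + k],
                                    elety = elety)
  cent <- colMeans(coords(select_atoms(s, chain = chains[1],
                                       warn_empty = FALSE)))
  hp <- helical_parameters(trk$transform, cent)
  hp$twist_deg <- hp$twist_deg / k
  hp$rise <- hp$rise / k
  hp$subunits_per_turn <- if (abs(hp$twist_deg) > 0)
    360 / abs(hp$twist_deg) else NA_real_
  hp$k <- k
  hp
}

#' Predict ring closure from helical parameters
#'
#' A helix closes into a ring of n subunits when n twists sum to a full
#' turn (within `tol_angle`) while the accumulated rise stays below
#' `tol_rise`.  Integers in `[3, n_max]` are scanned; the best n by
#' angular deviation wins, ties going to the smaller n.  FtsA
#' "mini-rings" correspond to n = 12-13 with near-zero rise.
#'
#' @param p a `helical_params` (or anything with `twist_deg` and
#'   `rise`).
#' @param tol_angle maximum `|360 - n * twist|`, degrees.
#' @param tol_rise maximum `|n * rise|`, Angstrom.
#' @param n_max largest subunit count scanned.
#' @return A `ring_closure`: `is_ring`, `n_subunits`,
#'   `closure_angle_dev_deg`, `closure_rise`.
#' @export
predict_ring_closure <- function(p, tol_angle = 3, tol_rise = 5,
                                 n_max = 100) {
  twist <- abs(p$twist_deg)
  if (twist == 0) {
    return(structure(list(is_ring = FALSE, n_subunits = NA_integer_,
                          closure_angle_dev_deg = NA_real_,
                          closure_rise = NA_real_),
                     class = "ring_closure"))
  }
  n <- 3:n_max
  dev <- abs(360 - n * twist)
  best <- n[which.min(dev)]            # which.min takes the first (smallest n)
  angle_dev <- abs(360 - best * twist)
  rise_tot <- abs(best * p$rise)
  structure(list(is_ring = angle_dev <= tol_angle && rise_tot <= tol_rise,
                 n_subunits = as.integer(best),
                 closure_angle_dev_deg = angle_dev,
                 closure_rise = rise_tot),
            class = "ring_closure")
}

#' @export
print.ring_closure <- function(x, ...) {
  if (is.na(x$n_subunits)) {
    cat("ring_closure: not a ring (zero twist)\n")
  } else {
    cat(sprintf(
      "ring_closure: %s, best n = %d (angle dev %.3f deg, rise %.3f A)\n",
      if (x$is_ring) "ring" else "helix", x$n_subunits,
      x$closure_angle_dev_deg, x$closure_rise))
  }
  invisible(x)
}

#' Expand a protomer along a screw operator
#'
#' Applies the operator 1..n times to the given chain(s), producing an
#' n+1-subunit helix (or ring).  A warning, not an error, is emitted on
#' severe steric overlap (minimum inter-subunit CA-CA distance < 1 A).
#'
#' @param s a [fil_structure()].
#' @param t the inter-subunit [rigid_transform()].
#' @param n number of applications (n >= 1).
#' @param chains source chains (default: all polymer chains).
#' @param chain_ids passed to [expand_assembly()].
#' @return Expanded [fil_structure()].
#' @export
expand_helix <- function(s, t, n, chains = NULL,
                         chain_ids = c("letters", "derived")) {
  stopifnot(n >= 1)
  chain_ids <- match.arg(chain_ids)
  if (is.null(chains)) chains <- polymer_chains(s)
  out <- expand_assembly(s, list(t), copies = n, chains = chains,
                         chain_ids = chain_ids)
  map <- attr(out, "chain_map")
  gen <- map$chain[map$copy > 0]
  ca <- select_atoms(out, elety = "CA", warn_empty = FALSE)
  if (nrow(ca) > 1 && length(gen)) {
    first <- coords(ca[ca$chain %in% chains, , drop = FALSE])
    second <- coords(ca[ca$chain %in% gen[1], , drop = FALSE])
    if (nrow(first) && nrow(second)) {
      d2 <- outer(rowSums(first^2), rowSums(second^2), "+") -
        2 * tcrossprod(first, second)
      if (min(d2) < 1)
        warning("expand_helix: severe steric overlap between subunits ",
                "(min CA-CA < 1 A)", call. = FALSE)
    }
  }
  out
}

#' Fit a circle to filament centroids (radius of curvature)
#'
#' Projects the points onto their best-fit plane (principal-component
#' plane) and fits a circle by linear least squares (Kasa fit) followed
#' by geometric Gauss-Newton refinement of the mean squared orthogonal
#' residual.  The radius is reported in nanometres, the convention used
#' for filament curvature.  Collinear input is flagged as infinite
#' radius rather than an error.
#'
#' @param centroids n x 3 matrix (Angstrom), n >= 3; e.g. from
#'   [chain_centroids()].
#' @param refine run the geometric refinement (default TRUE).
#' @return A `curvature_estimate`: `radius_nm`, `center` (3-vector, A),
#'   `plane_normal`, `residual_rmsd` (A, in-plane orthogonal residual),
#'   `n_points`, `infinite` (logical).
#' @export
fit_curvature <- function(centroids, refine = TRUE) {
  X <- as_coord_matrix(centroids)
  n <- nrow(X)
  if (n < 3) stop("fit_curvature: need at least 3 points, got ", n)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc)
  normal <- sv$v[, 3]
  if (is_collinear(Xc)) {
    return(structure(list(radius_nm = Inf, center = c(NA, NA, NA),
                          plane_normal = normal, residual_rmsd = NA_real_,
                          n_points = n, infinite = TRUE),
                     class = "curvature_estimate"))
  }
  P <- Xc %*% sv$v[, 1:2]                 # in-plane coordinates
  k <- kasa_circle(P)
  if (refine) k <- refine_circle(P, k)
  # guard: numerically straight arcs blow up the radius
  spread <- max(sv$d)
  if (!is.finite(k$r) || k$r > 1e6 * spread) {
    return(structure(list(radius_nm = Inf, center = c(NA, NA, NA),
                          plane_normal = normal, residual_rmsd = NA_real_,
                          n_points = n, infinite = TRUE),
                     class = "curvature_estimate"))
  }
  resid <- sqrt(rowSums(sweep(P, 2, k$c)^2)) - k$r
  center3 <- ctr + drop(sv$v[, 1:2] %*% k$c)
  structure(list(radius_nm = k$r / 10, center = center3,
                 plane_normal = normal,
                 residual_rmsd = sqrt(mean(resid^2)),
                 n_points = n, infinite = FALSE),
            class = "curvature_estimate")
}

#' @export
print.curvature_estimate <- function(x, ...) {
  if (x$infinite) {
    cat("curvature_estimate: straight (infinite radius), n =",
        x$n_points, "\n")
  } else {
    cat(sprintf(
      "curvature_estimate: radius %.2f nm (residual %.3f A, n = %d)\n",
      x$radius_nm, x$residual_rmsd, x$n_points))
  }
  invisible(x)
}

# algebraic circle fit (Kasa): linear LS on x^2+y^2 + D x + E y + F = 0
kasa_circle <- function(P) {
  A <- cbind(2 * P, 1)
  b <- rowSums(P^2)
  sol <- qr.solve(A, b)
  cc <- sol[1:2]
  r2 <- sol[3] + sum(cc^2)
  list(c = cc, r = sqrt(max(r2, 0)))
}

# Gauss-Newton on (cx, cy, r) minimising sum (|p - c| - r)^2
refine_circle <- function(P, k, iter = 50, tol = 1e-12) {
  cc <- k$c; r <- k$r
  for (i in seq_len(iter)) {
    d <- sweep(P, 2, cc)
    dist <- sqrt(rowSums(d^2))
    if (any(dist == 0)) break
    f <- dist - r
    J <- cbind(-d / dist, -1)
    step <- tryCatch(qr.solve(J, -f), error = function(e) NULL)
    if (is.null(step)) break
    cc <- cc + step[1:2]; r <- r + step[3]
    if (max(abs(step)) < tol * max(1, r)) break
  }
  list(c = cc, r = r)
}

#' Filament diameters about a screw axis
#'
#' Reports both the centroid-path diameter (twice the mean perpendicular
#' distance of subunit centroids from the axis -- the diameter of the
#' path traced by the subunit centres, used for comparisons with
#' ring/helix diameters measured on centre traces) and the envelope
#' diameter (twice the maximum perpendicular atom distance, the outer
#' extent of the filament).  The envelope is always at least the
#' centroid-path diameter.
#'
#' @param s an expanded [fil_structure()] (>= 2 subunits for a
#'   meaningful centroid path).
#' @param axis a `screw_axis` (or a list with `point` and `direction`).
#' @param chains chains treated as subunits (default: polymer chains).
#' @return List with `centroid_path_diameter_nm` and
#'   `envelope_diameter_nm`.
#' @export
filament_diameter <- function(s, axis, chains = NULL) {
  if (is.null(chains)) chains <- polymer_chains(s)
  cent <- chain_centroids(s, chains = chains)
  dc <- perp_distances(cent, axis$point, axis$direction)
  xyz <- coords(select_atoms(s, chain = chains, warn_empty = FALSE))
  da <- perp_distances(xyz, axis$point, axis$direction)
  list(centroid_path_diameter_nm = 2 * mean(dc) / 10,
       envelope_diameter_nm = 2 * max(da) / 10)
}

perp_distances <- function(X, point, direction) {
  u <- direction / sqrt(sum(direction^2))
  V <- sweep(as_coord_matrix(X), 2, as.numeric(point))
  par <- V %*% u
  sqrt(pmax(rowSums(V^2) - par^2, 0))
}
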