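#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rigid transform minimising the RMSD between a moving
#' and a fixed point set (rows in correspondence), using the SVD-based
#' Kabsch algorithm with the reflection corrected to guarantee a proper
#' rotation.  Unit weights are used throughout.
#'
#' @param moving,fixed n x 3 coordinate matrices with matching rows,
#'   n >= 3, not all collinear.  Data frames with columns `x`, `y`, `z`
#'   (e.g. from [select_atoms()]) are accepted.
#' @return A list of class `superposition`: `transform` (the
#'   [rigid_transform()] mapping `moving` onto `fixed`), `rmsd`
#'   (Angstrom) and `n` (number of points).
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(30), 10, 3)
#' y <- rt_apply(rt_from_screw(c(1, 1, 0), twist_deg = 40), x)
#' superpose(x, y)$rmsd
#' @export
superpose <- function(moving, fixed) {
  moving <- as_coord_matrix(moving)
  fixed <- as_coord_matrix(fixed)
  if (nrow(moving) != nrow(fixed))
    stop("superpose: row-count mismatch (", nrow(moving), " vs ",
         nrow(fixed), ")")
  n <- nrow(moving)
  if (n < 3) stop("superpose: need at least 3 points, got ", n)
  cm <- colMeans(moving)
  cf <- colMeans(fixed)
  A <- sweep(moving, 2, cm)
  B <- sweep(fixed, 2, cf)
  if (is_collinear(A) || is_collinear(B))
    stop("superpose: degenerate (collinear) point set")
  s <- svd(crossprod(A, B))          # A^T B = U D V^T
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- cf - drop(R %*% cm)
  transform <- rigid_transform(R, tr)
  resid <- rt_apply(transform, moving) - fixed
  out <- list(transform = transform,
              rmsd = sqrt(sum(resid^2) / n),
              n = n)
  class(out) <- "superposition"
  out
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: n = %d, rmsd = %.4f A\n", x$n, x$rmsd))
  invisible(x)
}

#' Inter-subunit transform within a structure
#'
#' Superposes the selected atoms of `chain_a` onto the equivalent atoms
#' of `chain_b`; the returned transform is the operator that carries
#' subunit `chain_a` onto subunit `chain_b` and is the input to
#' [screw_decompose()] and [helical_parameters()].  Atoms are put in
#' correspondence by (residue number, atom name); the intersection of
#' the two chains is used.
#'
#' @param s a [structure][read_structure()] object.
#' @param chain_a,chain_b chain identifiers.
#' @param elety atom names used for the superposition (default main
#'   chain N, CA, C).
#' @param resno optional residue numbers to restrict to.
#' @return A `superposition` (see [superpose()]) with an extra field
#'   `n_common` (number of matched atoms).
#' @export
transform_between_subunits <- function(s, chain_a, chain_b,
                                       elety = c("N", "CA", "C"),
                                       resno = NULL) {
  a <- select_atoms(s, chain = chain_a, elety = elety, resno = resno,
                    warn_empty = FALSE)
  b <- select_atoms(s, chain = chain_b, elety = elety, resno = resno,
                    warn_empty = FALSE)
  m <- match_atom_rows(a, b)
  if (nrow(m$a) < 3)
    stop("transform_between_subunits: only ", nrow(m$a),
         " atoms common to chains ", chain_a, " and ", chain_b)
  out <- superpose(coords(m$a), coords(m$b))
  out$n_common <- nrow(m$a)
  out
}

# align two atom-selection data frames on (resno, insert, elety)
match_atom_rows <- function(a, b) {
  key <- function(d) paste(d$resno, d$insert, d$elety, sep = "|")
  ka <- key(a); kb <- key(b)
  common <- intersect(ka, kb)
  ia <- match(common, ka)
  ib <- match(common, kb)
  list(a = a[ia, , drop = FALSE], b = b[ib, , drop = FALSE])
}

as_coord_matrix <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("x", "y", "z") %in% names(x)))
    x <- as.matrix(x[, c("x", "y", "z")])
  }
  x <- as.matrix(x)
  stopifnot(ncol(x) == 3, all(is.finite(x)))
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

# TRUE when centred points lie (numerically) on a line
is_collinear <- function(Ac, tol = 1e-8) {
  sv <- svd(Ac, nu = 0, nv = 0)$d
  sv[2] <= tol * max(sv[1], 1)
}
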