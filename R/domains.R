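#' Domain definitions
#'
#' A named map from domain names (for FtsA: IA, IB, IC, IIA, IIB; any
#' names are allowed) to lists of residue ranges in author numbering.
#' Ranges may be split (a domain assembled from several sequence
#' segments, as for the discontinuous actin-fold subdomains).  Ranges of
#' different domains must not overlap.
#'
#' The package ships an editable default for FtsA in
#' `system.file("extdata", "ftsa_domains.yaml", package = "protofil")`;
#' the shipped boundaries are an approximate assignment derived from
#' the actin-fold subdomain architecture of FtsA and are meant to be
#' replaced by structure-specific values where available.  All results
#' report the boundary set used.
#'
#' @param ranges named list; each element is a list/vector of ranges,
#'   each range a length-2 integer vector `c(from, to)` (a single range
#'   may be given flat, e.g. `list(IC = c(82, 160))`).
#' @param note free-text provenance note.
#' @return A `domain_definition`.
#' @export
domain_definition <- function(ranges, note = "") {
  stopifnot(is.list(ranges), length(names(ranges)) == length(ranges))
  ranges <- lapply(ranges, function(r) {
    if (!is.list(r)) r <- list(r)
    lapply(r, function(seg) {
      seg <- as.integer(seg)
      if (length(seg) != 2 || seg[1] > seg[2])
        stop("domain_definition: each range must be c(from, to)")
      seg
    })
  })
  all_res <- lapply(ranges, function(r)
    unlist(lapply(r, function(seg) seg[1]:seg[2])))
  for (i in seq_along(all_res)) {
    for (j in seq_len(i - 1L)) {
      ov <- intersect(all_res[[i]], all_res[[j]])
      if (length(ov))
        stop("domain_definition: domains ", names(ranges)[j], " and ",
             names(ranges)[i], " overlap at residues ",
             paste(utils::head(ov, 3), collapse = ","), "...")
    }
  }
  structure(list(ranges = ranges, note = note),
            class = "domain_definition")
}

#' @export
print.domain_definition <- function(x, ...) {
  cat("domain_definition:\n")
  for (nm in names(x$ranges)) {
    segs <- vapply(x$ranges[[nm]], function(s)
      paste0(s[1], "-", s[2]), character(1))
    cat(sprintf("  %-4s %s\n", nm, paste(segs, collapse = ", ")))
  }
  if (nzchar(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Residue numbers covered by one or more domains
#' @param domains a [domain_definition()].
#' @param names domain name(s).
#' @return Integer vector of residue numbers.
#' @export
domain_residues <- function(domains, names) {
  stopifnot(inherits(domains, "domain_definition"))
  missing_d <- setdiff(names, base::names(domains$ranges))
  if (length(missing_d))
    stop("domain_residues: unknown domain(s): ",
         paste(missing_d, collapse = ", "))
  sort(unique(unlist(lapply(domains$ranges[names], function(r)
    unlist(lapply(r, function(seg) seg[1]:seg[2]))))))
}

#' Read a domain definition from a YAML config
#'
#' Format: a mapping from domain name to a range `[from, to]` or a list
#' of ranges, with an optional top-level `note`.
#' @param path YAML file.
#' @return A [domain_definition()].
#' @export
read_domain_definition <- function(path) {
  y <- yaml::read_yaml(path)
  note <- if (!is.null(y$note)) y$note else ""
  y$note <- NULL
  ranges <- lapply(y, function(r) {
    if (is.list(r)) lapply(r, as.integer) else as.integer(r)
  })
  domain_definition(ranges, note = note)
}

#' Principal axes of a coordinate set
#'
#' Eigen-decomposition of the covariance (unit-mass second-moment
#' tensor) of the centred coordinates.  Axes are ordered by descending
#' spatial extent, so the first axis points along the longest dimension
#' of the point cloud and summarises domain orientation.  The default
#' sign convention makes each axis's largest-magnitude component
#' positive (deterministic but arbitrary; [domain_orientation()]
#' replaces it with a sequence-anchored convention).
#'
#' @param x n x 3 coordinates (matrix or `atom_selection`), n >= 3,
#'   non-collinear.
#' @return A `principal_axes_result`: `centroid`, `axes` (3x3 matrix,
#'   columns = axes), `moments` (descending variances, A^2),
#'   `degenerate` (TRUE when two moments are within 1% of each other).
#' @export
principal_axes <- function(x) {
  X <- as_coord_matrix(x)
  if (nrow(X) < 3) stop("principal_axes: need at least 3 points")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  if (is_collinear(Xc)) stop("principal_axes: collinear points")
  C <- crossprod(Xc) / nrow(Xc)
  e <- eigen(C, symmetric = TRUE)       # eigenvalues descending
  axes <- e$vectors
  for (k in 1:3) {                      # deterministic sign
    j <- which.max(abs(axes[, k]))
    if (axes[j, k] < 0) axes[, k] <- -axes[, k]
  }
  # re-impose right-handedness after sign fixing
  if (det(axes) < 0) axes[, 3] <- -axes[, 3]
  mom <- e$values
  rel <- abs(diff(mom)) / pmax(mom[-3], .Machine$double.eps)
  structure(list(centroid = ctr, axes = axes, moments = mom,
                 degenerate = any(rel < 0.01)),
            class = "principal_axes_result")
}

#' @export
print.principal_axes_result <- function(x, ...) {
  cat(sprintf(
    "principal_axes: moments %.2f / %.2f / %.2f A^2%s\n  first axis (%.3f, %.3f, %.3f)\n",
    x$moments[1], x$moments[2], x$moments[3],
    if (x$degenerate) " [degenerate]" else "",
    x$axes[1, 1], x$axes[2, 1], x$axes[3, 1]))
  invisible(x)
}

#' Orientation arrow of a domain
#'
#' Centroid plus signed first principal axis of the domain's main-chain
#' (N, CA, C) atoms.  The axis sign is fixed so that its dot product
#' with the vector from the centroid of the domain's N-terminal-half
#' residues to the centroid of its C-terminal-half residues is
#' non-negative, making arrows comparable across structures after
#' superposition on reference domains.
#'
#' @param s a [fil_structure()].
#' @param chain chain id.
#' @param domains a [domain_definition()].
#' @param domain_name the domain to orient (e.g. `"IC"`).
#' @param elety atom set (default main chain N, CA, C).
#' @return A list `domain_arrow`: `origin`, `direction` (unit),
#'   `domain`, `chain`, plus the underlying `principal_axes_result`.
#' @export
domain_orientation <- function(s, chain, domains, domain_name,
                               elety = c("N", "CA", "C")) {
  res <- domain_residues(domains, domain_name)
  sel <- select_atoms(s, chain = chain, resno = res, elety = elety,
                      warn_empty = FALSE)
  if (!nrow(sel))
    stop("domain_orientation: no atoms for domain ", domain_name,
         " in chain ", chain)
  present <- sort(unique(sel$resno))
  missing_res <- setdiff(res, present)
  if (length(missing_res) > length(res) / 2)
    stop("domain_orientation: domain ", domain_name, " mostly absent ",
         "from chain ", chain, " (missing residues ",
         paste(utils::head(missing_res, 5), collapse = ","), "...)")
  pa <- principal_axes(coords(sel))
  half <- present[ceiling(length(present) / 2)]
  n_half <- colMeans(coords(sel[sel$resno <= half, , drop = FALSE]))
  c_half <- colMeans(coords(sel[sel$resno > half, , drop = FALSE]))
  dir <- pa$axes[, 1]
  if (sum(dir * (c_half - n_half)) < 0) dir <- -dir
  structure(list(origin = pa$centroid, direction = dir,
                 domain = domain_name, chain = chain, axes = pa),
            class = "domain_arrow")
}

#' @export
print.domain_arrow <- function(x, ...) {
  cat(sprintf(
    "domain_arrow %s/%s: origin (%.1f, %.1f, %.1f), direction (%.3f, %.3f, %.3f)\n",
    x$chain, x$domain, x$origin[1], x$origin[2], x$origin[3],
    x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

#' Hinge rotation of a mobile domain between two conformers
#'
#' Measures how far a mobile domain rotates between two conformers of
#' the same protein: chain_b is superposed onto chain_a on the
#' main-chain atoms of the fixed domains, and the rotation that then
#' still superposes the mobile domain of (transformed) chain_b onto that
#' of chain_a is the hinge rotation.  This simplified two-superposition
#' analysis stands in for full dynamic-domain segmentation: it takes the
#' domain partition as input instead of deriving it from the
#' displacement field.
#'
#' @param s a [fil_structure()] containing both conformers (use
#'   separate chains; combine structures beforehand if needed).
#' @param chain_a,chain_b the two conformers.
#' @param domains a [domain_definition()].
#' @param fixed names of the fixed (reference) domains.
#' @param mobile name of the mobile domain.
#' @param elety atom set (default main chain N, CA, C).
#' @return A `hinge_result`: `angle_deg` in `[0, 180]`, `axis` (unit
#'   vector), `translation_A` (residual translation magnitude along the
#'   mobile superposition), `rmsd_fixed`, `rmsd_mobile`, `n_fixed`,
#'   `n_mobile`, `fixed_domains`, `mobile_domain`.
#' @export
hinge_rotation <- function(s, chain_a, chain_b, domains,
                           fixed = c("IA", "IIA", "IIB"), mobile = "IC",
                           elety = c("N", "CA", "C")) {
  res_fixed <- domain_residues(domains, fixed)
  res_mobile <- domain_residues(domains, mobile)
  sp_fixed <- transform_between_subunits(s, chain_b, chain_a,
                                         elety = elety, resno = res_fixed)
  if (sp_fixed$n_common < 3)
    stop("hinge_rotation: fewer than 3 fixed-domain atoms in common")
  # mobile-domain atoms of both conformers, chain_b moved into chain_a frame
  a_mob <- select_atoms(s, chain = chain_a, resno = res_mobile,
                        elety = elety, warn_empty = FALSE)
  b_mob <- select_atoms(s, chain = chain_b, resno = res_mobile,
                        elety = elety, warn_empty = FALSE)
  m <- match_atom_rows(a_mob, b_mob)
  if (nrow(m$a) < 3)
    stop("hinge_rotation: fewer than 3 mobile-domain atoms in common")
  b_in_a <- rt_apply(sp_fixed$transform, coords(m$b))
  sp_mob <- superpose(b_in_a, coords(m$a))
  ang <- rotation_angle(sp_mob$transform$rotation)
  ax <- rotation_axis(sp_mob$transform$rotation, ang)
  structure(list(angle_deg = ang, axis = ax,
                 translation_A = sqrt(sum(sp_mob$transform$translation^2)),
                 rmsd_fixed = sp_fixed$rmsd, rmsd_mobile = sp_mob$rmsd,
                 n_fixed = sp_fixed$n_common, n_mobile = nrow(m$a),
                 fixed_domains = fixed, mobile_domain = mobile,
                 chains = c(chain_a, chain_b)),
            class = "hinge_result")
}

#' @export
print.hinge_result <- function(x, ...) {
  cat(sprintf(
    "hinge_result %s vs %s: %s rotates %.2f deg (fixed: %s, rmsd %.2f A on %d atoms)\n",
    x$chains[1], x$chains[2], x$mobile_domain, x$angle_deg,
    paste(x$fixed_domains, collapse = "+"), x$rmsd_fixed, x$n_fixed))
  invisible(x)
}
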