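#' Synthetic ground-truth generators
#'
#' Every generator returns its inputs in a `truth_record` sufficient to
#' rebuild the output bit-identically (same arguments, same seed) and to
#' validate the analysis stack against known parameters: helices and
#' rings with known twist/rise/radius, antiparallel double filaments
#' with exact local C2 interfaces, arcs of known curvature radius, and
#' binding isotherms drawn from the package's response models.
#'
#' @name synthetic
NULL

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

truth_record <- function(generator, ...) {
  structure(list(generator = generator, params = list(...)),
            class = "truth_record")
}

#' @export
print.truth_record <- function(x, ...) {
  cat("truth_record:", x$generator, "\n")
  utils::str(x$params, max.level = 2, give.attr = FALSE)
  invisible(x)
}

#' Write a truth record as structured text (YAML)
#' @param tr a `truth_record`.
#' @param path output file.
#' @export
write_truth_record <- function(tr, path) {
  flat <- rapply(tr$params, function(v) {
    if (is.matrix(v)) as.numeric(t(v)) else v
  }, how = "replace")
  yaml::write_yaml(list(generator = tr$generator, params = flat), path)
  invisible(path)
}

#' Generate a rigid pseudo-protomer
#'
#' An asymmetric rigid pseudo-protein built from a smooth random walk of
#' CA positions with N, C and CB atoms attached in local frames, so that
#' every selector used on real structures (main chain, CB) works
#' unchanged.  The final coordinates are anisotropically scaled in the
#' principal frame until the three principal moments are pairwise
#' distinct by at least 5%, guaranteeing well-defined principal axes.
#' The protomer is centred at the origin.
#'
#' @param n_atoms total atom count (>= 4; four atoms per pseudo-residue).
#' @param seed RNG seed (the same seed reproduces the protomer
#'   bit-identically).
#' @return A [fil_structure()] with one chain `"A"`.
#' @export
make_protomer <- function(n_atoms = 96, seed = 1) {
  if (n_atoms < 4) stop("make_protomer: need n_atoms >= 4")
  n_res <- n_atoms %/% 4L
  with_seed(seed, {
    # compact confined walk: direction persistence plus a pull toward
    # the walk centroid keeps the pseudo-protomer globular
    r_conf <- 3.3 * max(n_res, 4)^(1 / 3) + 4
    dirs <- matrix(0, n_res + 2, 3)
    ca <- matrix(0, n_res + 2, 3)
    dirs[1, ] <- rand_unit()
    for (i in 2:(n_res + 2)) {
      pull <- -ca[i - 1, ] / r_conf
      dirs[i, ] <- norm1(0.45 * dirs[i - 1, ] + 0.9 * rand_unit() + pull)
      ca[i, ] <- ca[i - 1, ] + 3.8 * dirs[i, ]
    }
    ca <- ca[-1, , drop = FALSE]
    atoms <- vector("list", n_res)
    for (i in seq_len(n_res)) {
      t <- norm1(dirs[i + 1, ] + dirs[i, ])
      u <- norm1(pracma_nullvec(t))
      w <- cross3(t, u)
      atoms[[i]] <- rbind(
        N = ca[i, ] - 1.46 * norm1(t + 0.8 * u),
        CA = ca[i, ],
        C = ca[i, ] + 1.52 * norm1(t - 0.6 * u),
        CB = ca[i, ] + 1.53 * norm1(w + 0.3 * u))
    }
    X <- do.call(rbind, atoms)
    X <- distinct_moments(X)
    df <- data.frame(
      chain = "A",
      resno = rep(seq_len(n_res), each = 4),
      insert = "",
      resid = "ALA",
      elety = rep(c("N", "CA", "C", "CB"), n_res),
      elesy = rep(c("N", "C", "C", "C"), n_res),
      x = X[, 1], y = X[, 2], z = X[, 3],
      o = 1, alt = "", polymer = TRUE)
    fil_structure(df, id = sprintf("protomer_n%d_s%d", n_atoms, seed))
  })
}

rand_unit <- function() norm1(stats::rnorm(3))
norm1 <- function(v) v / sqrt(sum(v^2))
cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])
# any unit vector perpendicular to t
pracma_nullvec <- function(t) {
  ref <- if (abs(t[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  norm1(ref - sum(ref * t) * t)
}

# centre, rotate to principal frame, stretch until moments separate
distinct_moments <- function(X, min_sep = 0.05) {
  X <- sweep(X, 2, colMeans(X))
  for (k in 1:12) {
    e <- eigen(crossprod(X) / nrow(X), symmetric = TRUE)
    m <- e$values
    if (m[1] > (1 + min_sep) * m[2] && m[2] > (1 + min_sep) * m[3])
      return(X)
    X <- X %*% e$vectors %*% diag(c(1.12, 1.0, 0.88))
  }
  X
}

#' Build a helical filament from a protomer
#'
#' Subunit k sits at azimuth `k * twist` and height `k * rise`, its
#' centroid at distance `helical_radius` from the z axis.  The default
#' parameters place 13 subunits on a closed ring of 100 A centroid
#' radius (20 nm centroid-path diameter), the geometry of the dominant
#' 13-subunit FtsA "mini-ring".
#'
#' @param protomer a [fil_structure()] (e.g. [make_protomer()]).
#' @param rise rise per subunit, Angstrom.
#' @param twist twist per subunit, degrees.
#' @param helical_radius centroid distance from the axis, Angstrom.
#' @param n number of subunits (>= 2).
#' @return List: `structure` (a [fil_structure()], chains A, B, C, ...)
#'   and `truth` (a `truth_record` holding the generator operator).
#' @export
build_helical_filament <- function(protomer, rise = 0, twist = 360 / 13,
                                   helical_radius = 100, n = 13) {
  stopifnot(inherits(protomer, "fil_structure"), n >= 2)
  op <- rt_from_screw(c(0, 0, 1), c(0, 0, 0), twist, rise)
  base <- recentre(protomer, c(helical_radius, 0, 0))
  st <- place_subunits(base, lapply(seq_len(n) - 1L, rt_power, t = op),
                       id = "helical_filament")
  tr <- truth_record("helical_filament",
                     rise = rise, twist = twist,
                     helical_radius = helical_radius, n = n,
                     protomer_id = protomer$id,
                     operator = cbind(op$rotation, op$translation))
  list(structure = st, truth = tr)
}

# move a single-chain structure so its centroid is at `at`
recentre <- function(s, at = c(0, 0, 0)) {
  ctr <- colMeans(coords(s))
  apply_transform(s, rigid_transform(diag(3), at - ctr))
}

# lay copies of a (single-chain) structure under a list of transforms,
# naming chains A, B, C, ...
place_subunits <- function(base, ops, id, chains = NULL) {
  pool <- c(LETTERS, letters, as.character(0:9))
  if (is.null(chains)) chains <- pool[seq_along(ops)]
  pieces <- lapply(seq_along(ops), function(k) {
    a <- apply_transform(base, ops[[k]])$atoms
    a$chain <- chains[k]
    a
  })
  fil_structure(do.call(rbind, pieces), id = id)
}

#' Build an antiparallel double filament with exact local C2 interfaces
#'
#' The first protofilament runs along z (subunit k at height `k * rise`,
#' centroid line at y = +`gap`/2); the second is its exact 180-degree
#' rotation about an axis along x.  By construction every lateral
#' interface then has exact local C2 symmetry, and subunits of opposing
#' protofilaments are antiparallel (relative twist 180 degrees).  With
#' `registry = "aligned"` the C2 axis height is chosen so opposing
#' subunits pair at equal heights (the i-i* registry, with diagonal
#' i-i*-1 contacts when the protomer is long enough); `"half"` offsets
#' the protofilaments by half a longitudinal repeat.
#'
#' When `rise` or `gap` is `NULL` it is chosen by bisection as the most
#' open spacing at which consecutive (resp. opposing) subunits still
#' share at least `contact_pairs` residue pairs within `contact_cutoff`
#' Angstrom, guaranteeing that the built interfaces are detectable with
#' a margin.
#'
#' @param protomer a [fil_structure()].
#' @param n subunits per protofilament (>= 2).
#' @param rise longitudinal repeat, Angstrom, or `NULL` for automatic
#'   contact-based spacing.
#' @param gap distance between the two protofilament centroid lines,
#'   Angstrom, or `NULL` for automatic spacing.
#' @param registry `"aligned"` or `"half"`.
#' @param contact_pairs,contact_cutoff spacing calibration (see above).
#' @return List: `structure` (protofilament 1 = chains A, B, ...;
#'   protofilament 2 = chains a, b, ...) and `truth`, whose
#'   `interfaces` element lists every built interface with its class
#'   and, for lateral interfaces, the exact local C2 axis.
#' @export
build_double_filament <- function(protomer, n = 4, rise = NULL,
                                  gap = NULL,
                                  registry = c("aligned", "half"),
                                  contact_pairs = 10,
                                  contact_cutoff = 4.0) {
  stopifnot(inherits(protomer, "fil_structure"), n >= 2)
  registry <- match.arg(registry)
  base <- recentre(protomer)
  X <- coords(base)
  zext <- diff(range(X[, 3]))

  if (is.null(rise)) {
    rise <- calibrate_spacing(
      function(r) count_contact_pairs(base, shift = c(0, 0, r),
                                      cutoff = contact_cutoff),
      lo = 0.4 * zext, hi = zext + 20, target = contact_pairs)
    if (is.na(rise))
      stop("build_double_filament: no rise achieves the requested ",
           "longitudinal contact; pass rise=")
  }
  z_mid <- (n - 1) * rise / 2 + if (registry == "half") rise / 4 else 0

  if (is.null(gap)) {
    yext <- diff(range(X[, 2]))
    # the second protofilament sits at -y relative to the first, so the
    # calibration probe must approach from that side.  The probe is the
    # *farther* lateral neighbour (height offset one repeat for the
    # aligned registry, half a repeat for the half registry): if that
    # contact holds with margin, the nearer same-height contact holds a
    # fortiori, so each subunit touches two opposing subunits -- the
    # double-filament contact pattern
    dz <- if (registry == "aligned") rise else rise / 2
    probe <- function(dz0) function(g) count_contact_pairs(
      base, shift = c(0, -g, dz0), flipx = TRUE,
      cutoff = contact_cutoff)
    gap <- calibrate_spacing(probe(dz), lo = 0.2 * yext,
                             hi = yext + 20, target = contact_pairs)
    if (is.na(gap)) {
      # protomer too short along z for the offset contact: calibrate on
      # the same-height neighbour instead (single lateral registry)
      gap <- calibrate_spacing(probe(0), lo = 0.2 * yext,
                               hi = yext + 20, target = contact_pairs)
    }
    if (is.na(gap))
      stop("build_double_filament: no gap achieves the requested ",
           "lateral contact; use a larger protomer or pass gap=")
  }

  base1 <- recentre(protomer, c(0, gap / 2, 0))
  ops1 <- lapply(seq_len(n) - 1L, function(k)
    rigid_transform(diag(3), c(0, 0, k * rise)))
  c2 <- rt_from_screw(c(1, 0, 0), c(0, 0, z_mid), 180, 0)
  ops2 <- lapply(ops1, function(op) rt_compose(c2, op))
  pf1 <- place_subunits(base1, ops1, id = "df", chains = LETTERS[1:n])
  pf2 <- place_subunits(base1, ops2, id = "df", chains = letters[1:n])
  st <- fil_structure(rbind(pf1$atoms, pf2$atoms),
                      id = "double_filament")

  truth_ifaces <- enumerate_truth_interfaces(st, n, rise, z_mid,
                                             contact_cutoff = 4.5,
                                             min_pairs = 5)
  tr <- truth_record("double_filament",
                     n_per_protofilament = n, rise = rise, gap = gap,
                     registry = registry, z_mid = z_mid,
                     c2_axis = list(direction = c(1, 0, 0),
                                    point = c(0, 0, z_mid)),
                     protomer_id = protomer$id,
                     interfaces = truth_ifaces)
  list(structure = st, truth = tr)
}

# largest spacing x with pair count >= target (count decreases with x);
# NA when even the closest spacing cannot achieve the target
calibrate_spacing <- function(count_at, lo, hi, target, iter = 40) {
  if (count_at(hi) >= target) return(hi)
  if (count_at(lo) < target) return(NA_real_)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (count_at(mid) >= target) lo <- mid else hi <- mid
  }
  lo
}

count_contact_pairs <- function(base, shift, cutoff, flipx = FALSE) {
  a <- select_atoms(base, warn_empty = FALSE)
  b <- a
  xb <- coords(b)
  if (flipx) xb[, 2:3] <- -xb[, 2:3]           # 180 deg about x
  xb <- sweep(xb, 2, shift, "+")
  b[, c("x", "y", "z")] <- xb
  nrow(chain_pair_contacts(a, b, cutoff, cutoff)$contact_pairs)
}

# list the interfaces present in the noiseless construction, classed by
# construction geometry (height offset for lateral, adjacency for
# longitudinal), including exact C2 axes for lateral interfaces
enumerate_truth_interfaces <- function(st, n, rise, z_mid,
                                       contact_cutoff, min_pairs) {
  pf1 <- LETTERS[1:n]; pf2 <- letters[1:n]
  hgt <- function(ch) mean(coords(select_atoms(st, chain = ch,
                                               warn_empty = FALSE))[, 3])
  out <- list()
  add <- function(c1, c2, class, c2_axis = NULL) {
    sel1 <- select_atoms(st, chain = c1, warn_empty = FALSE)
    sel2 <- select_atoms(st, chain = c2, warn_empty = FALSE)
    np <- nrow(chain_pair_contacts(sel1, sel2, contact_cutoff,
                                   contact_cutoff)$contact_pairs)
    if (np >= min_pairs)
      out[[length(out) + 1L]] <<- list(
        chains = sort(c(c1, c2)), class = class, n_pairs = np,
        c2_axis = c2_axis)
  }
  for (k in seq_len(n - 1)) add(pf1[k], pf1[k + 1], "longitudinal")
  for (k in seq_len(n - 1)) add(pf2[k], pf2[k + 1], "longitudinal")
  for (j in seq_len(n)) {
    zj <- hgt(pf1[j])
    for (k in seq_len(n)) {
      off <- abs(hgt(pf2[k]) - zj) / rise
      class <- if (off < 0.25) "lateral_i_istar"
               else if (off < 1.25) "lateral_i_istar_minus1"
               else "lateral_other"
      axis_z <- (zj + hgt(pf2[k])) / 2
      add(pf1[j], pf2[k], class,
          c2_axis = list(direction = c(1, 0, 0),
                         point = c(0, 0, axis_z)))
    }
  }
  out
}

#' Build an arc-shaped (bent) filament
#'
#' Subunit centroids lie exactly on a circle of the stated radius in the
#' xy plane, consecutive centroids separated by `spacing_A` of arc
#' length -- the geometry of a filament bent with constant curvature.
#' The default radius mirrors a gently curved tetramer-scale filament.
#'
#' @param protomer a [fil_structure()].
#' @param curvature_radius_nm circle radius, nanometres.
#' @param spacing_A arc-length spacing between centroids, Angstrom
#'   (must be below the circumference).
#' @param n subunits (>= 3).
#' @return List: `structure`, `truth`.
#' @export
build_arc_filament <- function(protomer, curvature_radius_nm = 16.3,
                               spacing_A = 48, n = 6) {
  stopifnot(inherits(protomer, "fil_structure"), n >= 3)
  R <- curvature_radius_nm * 10
  if (spacing_A >= 2 * pi * R)
    stop("build_arc_filament: spacing exceeds the circumference")
  step_deg <- spacing_A / R * 180 / pi
  base <- recentre(protomer, c(R, 0, 0))
  ops <- lapply(seq_len(n) - 1L, function(k)
    rt_from_screw(c(0, 0, 1), c(0, 0, 0), k * step_deg, 0))
  st <- place_subunits(base, ops, id = "arc_filament")
  tr <- truth_record("arc_filament",
                     curvature_radius_nm = curvature_radius_nm,
                     spacing_A = spacing_A, n = n,
                     center = c(0, 0, 0), plane_normal = c(0, 0, 1),
                     protomer_id = protomer$id)
  list(structure = st, truth = tr)
}

#' Add Gaussian coordinate noise
#'
#' Independent N(0, sigma^2) displacements on every coordinate of every
#' atom; deterministic under `seed`.
#'
#' @param s a [fil_structure()].
#' @param sigma_A standard deviation per coordinate, Angstrom.
#' @param seed RNG seed.
#' @return A [fil_structure()] with perturbed coordinates.
#' @export
perturb <- function(s, sigma_A, seed = 1) {
  stopifnot(inherits(s, "fil_structure"), sigma_A >= 0)
  if (sigma_A == 0) return(s)
  with_seed(seed, {
    n <- nrow(s$atoms)
    s$atoms[, c("x", "y", "z")] <- s$atoms[, c("x", "y", "z")] +
      matrix(stats::rnorm(3 * n, 0, sigma_A), n, 3)
    s
  })
}

#' Simulate a binding isotherm
#'
#' Draws responses from the single-site ([spr_response()]) or two-step
#' ([fp_anisotropy()]) model with i.i.d. Gaussian response noise.  The
#' default parameters are the conditions of the FtsA-FtsN titrations:
#' single-site Kd 0.8 uM; two-step Kd pair 0.016 and 11 uM.
#'
#' @param model `"single_site"` or `"two_step"`.
#' @param params named list of model parameters (defaults above).
#' @param concentrations titrant concentrations, uM (default: 12-point
#'   1:2 dilution from 10 uM for single-site; 12-point 1:3 dilution
#'   from 100 uM for two-step).
#' @param noise_sigma response noise s.d. (same units as the response).
#' @param seed RNG seed.
#' @return List: `data` (an [isotherm()]) and `truth`.
#' @export
simulate_isotherm <- function(model = c("single_site", "two_step"),
                              params = NULL, concentrations = NULL,
                              noise_sigma = 0, seed = 1) {
  model <- match.arg(model)
  if (model == "single_site") {
    if (is.null(params)) params <- list(Kd = 0.8, Rmax = 100, B = 0)
    if (is.null(concentrations))
      concentrations <- dilution_series(10, 12, 2)
    y0 <- spr_response(concentrations, params$Kd, params$Rmax, params$B)
  } else {
    if (is.null(params))
      params <- list(F0 = 0.10, F_Lo = 0.08, Kd_Lo = 0.016,
                     F_Hi = 0.12, Kd_Hi = 11)
    if (is.null(concentrations))
      concentrations <- dilution_series(100, 12, 3)
    y0 <- fp_anisotropy(concentrations, params$F0, params$F_Lo,
                        params$Kd_Lo, params$F_Hi, params$Kd_Hi)
  }
  y <- if (noise_sigma > 0) {
    with_seed(seed, y0 + stats::rnorm(length(y0), 0, noise_sigma))
  } else y0
  list(data = isotherm(concentrations, y),
       truth = truth_record("isotherm", model = model, params = params,
                            concentrations = concentrations,
                            noise_sigma = noise_sigma, seed = seed))
}

#' Serial dilution series
#' @param top highest concentration.
#' @param n number of points.
#' @param factor dilution factor between consecutive points.
#' @return Numeric vector, ascending.
#' @export
dilution_series <- function(top, n, factor = 2) {
  sort(top / factor^(seq_len(n) - 1))
}
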