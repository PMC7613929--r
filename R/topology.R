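#' Detect inter-subunit interfaces
#'
#' Two chains form an interface when at least `min_pairs` residue pairs
#' have a minimum heavy-atom distance of at most `contact_cutoff`
#' Angstrom (4.5 A and 5 pairs by default, standard quaternary-contact
#' practice).  A centroid-distance prefilter skips chain pairs that
#' cannot be in contact.
#'
#' @param s a [fil_structure()].
#' @param contact_cutoff heavy-atom distance cutoff, Angstrom.
#' @param min_pairs minimum number of residue pairs within the cutoff.
#' @param polar_cutoff N/O-N/O distance defining a polar contact, A.
#' @param chains chains to consider (default: all polymer chains).
#' @param min_residues passed to [polymer_chains()]; short peptide
#'   chains below this residue count are left out of the topology.
#' @return List of `interface_contact` records: `chains` (sorted pair),
#'   `contact_pairs` (data frame: resno1, resid1, resno2, resid2, dist),
#'   `n_residue_pairs`, and `polar_contacts` (atom-level N/O pairs).
#' @export
find_interfaces <- function(s, contact_cutoff = 4.5, min_pairs = 5,
                            polar_cutoff = 3.5, chains = NULL,
                            min_residues = 1) {
  stopifnot(inherits(s, "fil_structure"))
  if (is.null(chains)) chains <- polymer_chains(s, min_residues)
  if (length(chains) < 2) {
    warning("find_interfaces: fewer than two polymer chains")
    return(list())
  }
  chains <- sort(chains)
  sel <- lapply(chains, function(ch)
    select_atoms(s, chain = ch, warn_empty = FALSE))
  names(sel) <- chains
  cent <- t(vapply(sel, function(a) colMeans(coords(a)), numeric(3)))
  rad <- vapply(seq_along(sel), function(i) {
    sqrt(max(rowSums(sweep(coords(sel[[i]]), 2, cent[i, ])^2)))
  }, numeric(1))

  out <- list()
  for (i in seq_along(chains)[-length(chains)]) {
    for (j in (i + 1):length(chains)) {
      dc <- sqrt(sum((cent[i, ] - cent[j, ])^2))
      if (dc - rad[i] - rad[j] > contact_cutoff) next
      iface <- chain_pair_contacts(sel[[i]], sel[[j]], contact_cutoff,
                                   polar_cutoff)
      if (nrow(iface$contact_pairs) >= min_pairs) {
        out[[length(out) + 1L]] <- structure(
          list(chains = c(chains[i], chains[j]),
               contact_pairs = iface$contact_pairs,
               n_residue_pairs = nrow(iface$contact_pairs),
               polar_contacts = iface$polar_contacts),
          class = "interface_contact")
      }
    }
  }
  out
}

# residue-pair minimum distances and polar atom pairs for one chain pair
chain_pair_contacts <- function(a, b, contact_cutoff, polar_cutoff) {
  xa <- coords(a); xb <- coords(b)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  d2[d2 < 0] <- 0
  hit <- which(d2 <= contact_cutoff^2, arr.ind = TRUE)
  if (!nrow(hit)) {
    return(list(contact_pairs = empty_contact_pairs(),
                polar_contacts = empty_polar_contacts()))
  }
  dd <- sqrt(d2[hit])
  key <- paste(a$resno[hit[, 1]], b$resno[hit[, 2]], sep = "|")
  best <- tapply(seq_along(dd), key, function(ii) ii[which.min(dd[ii])])
  best <- unlist(best, use.names = FALSE)
  cp <- data.frame(resno1 = a$resno[hit[best, 1]],
                   resid1 = a$resid[hit[best, 1]],
                   resno2 = b$resno[hit[best, 2]],
                   resid2 = b$resid[hit[best, 2]],
                   dist = dd[best])
  cp <- cp[order(cp$dist), ]
  rownames(cp) <- NULL

  pol_i <- a$elesy[hit[, 1]] %in% c("N", "O") &
    b$elesy[hit[, 2]] %in% c("N", "O") & dd <= polar_cutoff
  pc <- if (any(pol_i)) {
    hp <- hit[pol_i, , drop = FALSE]
    data.frame(resno1 = a$resno[hp[, 1]], atom1 = a$elety[hp[, 1]],
               resno2 = b$resno[hp[, 2]], atom2 = b$elety[hp[, 2]],
               dist = dd[pol_i])
  } else empty_polar_contacts()
  pc <- pc[order(pc$dist), ]
  rownames(pc) <- NULL
  list(contact_pairs = cp, polar_contacts = pc)
}

empty_contact_pairs <- function()
  data.frame(resno1 = integer(), resid1 = character(),
             resno2 = integer(), resid2 = character(), dist = numeric())
empty_polar_contacts <- function()
  data.frame(resno1 = integer(), atom1 = character(),
             resno2 = integer(), atom2 = character(), dist = numeric())

#' @export
print.interface_contact <- function(x, ...) {
  cat(sprintf("interface %s-%s: %d residue pairs, %d polar contacts, min %.2f A\n",
              x$chains[1], x$chains[2], x$n_residue_pairs,
              nrow(x$polar_contacts),
              if (x$n_residue_pairs) min(x$contact_pairs$dist) else NA))
  invisible(x)
}

#' Polar contacts across an interface
#'
#' Inter-chain nitrogen/oxygen atom pairs within `polar_cutoff`
#' (donor/acceptor geometry is not checked).  Counts are comparable
#' across structures and quantify hydrogen-bond loss between straight
#' and bent filament interfaces.
#'
#' @param s a [fil_structure()].
#' @param iface an `interface_contact` (or a 2-vector of chain ids).
#' @param polar_cutoff Angstrom.
#' @return Data frame of atom pairs with distances.
#' @export
polar_contacts <- function(s, iface, polar_cutoff = 3.5) {
  ch <- if (inherits(iface, "interface_contact")) iface$chains else iface
  a <- select_atoms(s, chain = ch[1], warn_empty = FALSE)
  b <- select_atoms(s, chain = ch[2], warn_empty = FALSE)
  a <- a[a$elesy %in% c("N", "O"), , drop = FALSE]
  b <- b[b$elesy %in% c("N", "O"), , drop = FALSE]
  if (!nrow(a) || !nrow(b)) return(empty_polar_contacts())
  chain_pair_contacts(a, b, polar_cutoff, polar_cutoff)$polar_contacts
}

#' Classify an interface as longitudinal or lateral
#'
#' The relative twist between the two subunits (rotation angle of the
#' transform superposing one onto the other) separates longitudinal
#' contacts between near-parallel consecutive subunits (twist below
#' `longitudinal_twist_max`) from lateral contacts between antiparallel
#' subunits of opposing protofilaments (twist within
#' `lateral_twist_range`).  Longitudinal contacts are subdivided into
#' tight/loose by the number of inter-subunit residue pairs between one
#' subunit's IIA/IIB domains and the next subunit's nucleotide face; the
#' two lateral registries (i-i* vs i-i*-1) are separated by the offset
#' of the inter-centroid vector along the protofilament axis, measured
#' against half the longitudinal repeat.
#'
#' @param s a [fil_structure()].
#' @param iface an `interface_contact` from [find_interfaces()].
#' @param domains a [domain_definition()] (may be `NULL`: tight/loose
#'   and contact-concentration evidence then unavailable).
#' @param longitudinal_twist_max degrees; default 60.
#' @param lateral_twist_range degrees; default `c(150, 180)`.
#' @param tight_min_pairs IIA/IIB-to-nucleotide-face residue pairs
#'   required to call a longitudinal contact tight; default 3.
#' @param longitudinal_repeat longitudinal rise in Angstrom used for the
#'   lateral registry threshold; when `NULL` the offset itself decides
#'   (registry "i-i*" when the axial offset is below half the observed
#'   minimum inter-centroid distance).
#' @param axis protofilament axis direction (unit 3-vector); when
#'   `NULL`, the first principal axis of the two subunit centroids'
#'   parent structure is used.
#' @return An `interface_class`: `label` in
#'   `c("longitudinal_tight", "longitudinal_loose", "lateral_i_istar",
#'   "lateral_i_istar_minus1", "other")`, `relative_twist_deg`, and an
#'   `evidence` list.
#' @export
classify_interface <- function(s, iface, domains = NULL,
                               longitudinal_twist_max = 60,
                               lateral_twist_range = c(150, 180),
                               tight_min_pairs = 3,
                               longitudinal_repeat = NULL,
                               axis = NULL) {
  stopifnot(inherits(iface, "interface_contact"))
  ch <- iface$chains
  tr <- transform_between_subunits(s, ch[1], ch[2])
  twist <- abs(screw_decompose(tr$transform)$twist_deg)
  evidence <- list(superposition_rmsd = tr$rmsd, n_common = tr$n_common)

  label <- "other"
  if (twist <= longitudinal_twist_max) {
    label <- "longitudinal_loose"
    if (!is.null(domains)) {
      n_tight <- tight_contact_pairs(iface, domains)
      evidence$tight_pairs <- n_tight
      if (n_tight >= tight_min_pairs) label <- "longitudinal_tight"
    } else {
      evidence$tight_pairs <- NA
    }
  } else if (twist >= lateral_twist_range[1] &&
             twist <= lateral_twist_range[2]) {
    cent <- chain_centroids(s, chains = ch)
    dvec <- cent[2, ] - cent[1, ]
    u <- if (!is.null(axis)) axis / sqrt(sum(axis^2)) else {
      pc <- principal_axes(coords(select_atoms(s, chain = ch,
                                               warn_empty = FALSE)))
      pc$axes[, 1]
    }
    offset <- abs(sum(dvec * u))
    evidence$registry_offset <- offset
    thresh <- if (!is.null(longitudinal_repeat)) {
      longitudinal_repeat / 4   # midpoint of [0, repeat/2]
    } else {
      sqrt(sum(dvec^2)) / 4
    }
    evidence$registry_threshold <- thresh
    label <- if (offset <= thresh) "lateral_i_istar"
             else "lateral_i_istar_minus1"
    if (!is.null(domains)) {
      evidence$ic_fraction <- domain_contact_fraction(iface, domains, "IC")
    }
  }
  structure(list(label = label, relative_twist_deg = twist,
                 chains = ch, evidence = evidence),
            class = "interface_class")
}

#' @export
print.interface_class <- function(x, ...) {
  cat(sprintf("interface %s-%s: %s (relative twist %.1f deg)\n",
              x$chains[1], x$chains[2], x$label, x$relative_twist_deg))
  invisible(x)
}

# residue pairs joining IIA/IIB of either subunit to the nucleotide face
# (IA/IB by default) of the other
tight_contact_pairs <- function(iface, domains,
                                tail_domains = c("IIA", "IIB"),
                                face_domains = NULL) {
  if (is.null(face_domains))
    face_domains <- intersect(c("IA", "IB"), names(domains$ranges))
  tail_res <- domain_residues(domains, tail_domains)
  face_res <- domain_residues(domains, face_domains)
  cp <- iface$contact_pairs
  sum((cp$resno1 %in% tail_res & cp$resno2 %in% face_res) |
      (cp$resno1 %in% face_res & cp$resno2 %in% tail_res) |
      (cp$resno1 %in% tail_res & cp$resno2 %in% tail_res))
}

domain_contact_fraction <- function(iface, domains, domain_name) {
  res <- domain_residues(domains, domain_name)
  cp <- iface$contact_pairs
  if (!nrow(cp)) return(NA_real_)
  mean(cp$resno1 %in% res & cp$resno2 %in% res)
}

#' Test an interface for local twofold (C2) symmetry
#'
#' An interface has local C2 symmetry when a 180-degree rotation about
#' some axis swaps the two chains while mapping the dimer onto itself.
#' The chain-swap self-superposition of the dimer is computed (chain A
#' onto chain B and vice versa, simultaneously) and screw-decomposed;
#' the interface passes when the rotation is within `tol_angle` of 180
#' degrees, the residual screw rise is below `tol_rise` and the mapping
#' RMSD is below `tol_rmsd`.  Local symmetry in a crystal is
#' approximate, hence the permissive defaults.
#'
#' @param s a [fil_structure()].
#' @param iface an `interface_contact` or 2-vector of chain ids.
#' @param elety atom names used for the mapping (default main chain).
#' @param tol_angle,tol_rise,tol_rmsd acceptance tolerances (degrees,
#'   Angstrom, Angstrom).
#' @return A `c2_assessment`: `has_c2`, `axis` (a `screw_axis`),
#'   `angle_dev_deg`, `rise_abs`, `mapping_rmsd`.
#' @export
detect_c2 <- function(s, iface, elety = c("N", "CA", "C"),
                      tol_angle = 5, tol_rise = 1.5, tol_rmsd = 2.0) {
  ch <- if (inherits(iface, "interface_contact")) iface$chains else iface
  a <- select_atoms(s, chain = ch[1], elety = elety, warn_empty = FALSE)
  b <- select_atoms(s, chain = ch[2], elety = elety, warn_empty = FALSE)
  m <- match_atom_rows(a, b)
  if (nrow(m$a) < 3)
    stop("detect_c2: fewer than 3 atoms shared between chains ",
         ch[1], " and ", ch[2])
  moving <- rbind(coords(m$a), coords(m$b))
  fixed <- rbind(coords(m$b), coords(m$a))
  sp <- superpose(moving, fixed)
  ax <- screw_decompose(sp$transform)
  angle_dev <- abs(abs(ax$twist_deg) - 180)
  rise_abs <- abs(ax$rise)
  has_c2 <- angle_dev <= tol_angle && rise_abs <= tol_rise &&
    sp$rmsd <= tol_rmsd
  structure(list(has_c2 = has_c2, axis = ax, angle_dev_deg = angle_dev,
                 rise_abs = rise_abs, mapping_rmsd = sp$rmsd,
                 chains = ch),
            class = "c2_assessment")
}

#' @export
print.c2_assessment <- function(x, ...) {
  cat(sprintf(
    "C2 %s-%s: %s (angle dev %.2f deg, rise %.2f A, rmsd %.2f A)\n",
    x$chains[1], x$chains[2], if (x$has_c2) "yes" else "no",
    x$angle_dev_deg, x$rise_abs, x$mapping_rmsd))
  invisible(x)
}

#' Assemble the filament graph
#'
#' Subunits are nodes; classified interfaces are edges.  Protofilaments
#' are the connected components of the longitudinal subgraph, reported
#' as ordered simple paths (or closed rings when the longitudinal edges
#' form a cycle; a cycle is a valid filament topology, not an error).
#' A component is flagged as a double filament when it holds exactly
#' two protofilaments joined laterally by at least one lateral edge per
#' two subunits.
#'
#' @param interfaces list of `interface_contact` records.
#' @param classes list of `interface_class` records, parallel to
#'   `interfaces` (e.g. from [classify_interface()]).
#' @return A `filament_graph`: `graph` (igraph), `edges` (data frame),
#'   `protofilaments` (list of: chains in path order, closed flag),
#'   `components` (data frame: id, size, n_lateral, n_longitudinal,
#'   double_filament).
#' @export
build_filament_graph <- function(interfaces, classes) {
  stopifnot(length(interfaces) == length(classes))
  if (!length(interfaces))
    stop("build_filament_graph: no interfaces")
  edges <- data.frame(
    chain1 = vapply(interfaces, function(i) i$chains[1], character(1)),
    chain2 = vapply(interfaces, function(i) i$chains[2], character(1)),
    label = vapply(classes, function(c) c$label, character(1)),
    twist = vapply(classes, function(c) c$relative_twist_deg, numeric(1)),
    n_pairs = vapply(interfaces, function(i) i$n_residue_pairs,
                     numeric(1)))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  long <- igraph::subgraph_from_edges(
    g, igraph::E(g)[grepl("^longitudinal", edges$label)],
    delete.vertices = FALSE)

  protos <- lapply(
    igraph::decompose(long, min.vertices = 1), function(cc) {
      vs <- igraph::V(cc)$name
      if (!igraph::ecount(cc))
        return(list(chains = vs, closed = FALSE))
      deg <- igraph::degree(cc)
      if (all(deg == 2)) {                       # closed ring
        path <- ring_order(cc)
        return(list(chains = path, closed = TRUE))
      }
      ends <- names(deg)[deg == 1]
      if (length(ends) != 2) {      # branched: no unique path order
        warning("build_filament_graph: branched longitudinal component (",
                paste(utils::head(vs, 5), collapse = ","),
                "...); path order undefined", call. = FALSE)
        return(list(chains = vs, closed = FALSE))
      }
      path <- igraph::shortest_paths(cc, from = ends[1],
                                     to = ends[2])$vpath[[1]]
      list(chains = igraph::V(cc)$name[as.integer(path)], closed = FALSE)
    })

  comp <- igraph::components(g)
  comp_df <- do.call(rbind, lapply(seq_len(comp$no), function(k) {
    vs <- names(comp$membership)[comp$membership == k]
    in_comp <- edges$chain1 %in% vs
    n_lat <- sum(in_comp & grepl("^lateral", edges$label))
    n_long <- sum(in_comp & grepl("^longitudinal", edges$label))
    pf_in <- Filter(function(p) all(p$chains %in% vs), protos)
    data.frame(id = k, size = length(vs), n_longitudinal = n_long,
               n_lateral = n_lat, n_protofilaments = length(pf_in),
               double_filament = length(pf_in) == 2 &&
                 n_lat >= length(vs) / 2)
  }))
  structure(list(graph = g, edges = edges, protofilaments = protos,
                 components = comp_df),
            class = "filament_graph")
}

ring_order <- function(cc) {
  vs <- igraph::V(cc)$name
  path <- vs[1]
  prev <- NA_character_
  repeat {
    nb <- igraph::neighbors(cc, path[length(path)])$name
    nxt <- setdiff(nb, prev)[1]
    if (nxt == path[1]) break
    prev <- path[length(path)]
    path <- c(path, nxt)
  }
  path
}

#' @export
print.filament_graph <- function(x, ...) {
  cat("filament_graph:", igraph::vcount(x$graph), "subunits,",
      nrow(x$edges), "interfaces\n")
  for (p in x$protofilaments)
    cat("  protofilament", if (p$closed) "(closed ring)" else "",
        ":", paste(p$chains, collapse = "-"), "\n")
  print(x$components, row.names = FALSE)
  invisible(x)
}
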