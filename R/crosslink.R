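#' Thiol cross-linker specification
#'
#' Expected bridging distance (span) and tolerance of a bis-thiol
#' reactive cross-linker.  Only BMOE's ~8 A span is widely quoted in
#' running text; spans for other linkers (dBBr, BMB, BMH, ...) must be
#' supplied by the user, e.g. via [read_linker_table()].  A candidate
#' pair is *compatible* with a linker when its Cbeta-Cbeta distance is
#' at most span + tolerance; pairs much shorter than the span are
#' flagged, since a short pair may cross-link better with a shorter
#' reagent.
#'
#' @param name linker name.
#' @param span expected cross-linking distance, Angstrom (> 0).
#' @param tolerance Angstrom (default 3).
#' @return A `linker_spec`.
#' @export
linker_spec <- function(name, span, tolerance = 3) {
  stopifnot(is.character(name), length(name) == 1, span > 0,
            tolerance >= 0)
  structure(list(name = name, span = span, tolerance = tolerance),
            class = "linker_spec")
}

#' Read a linker table from YAML
#'
#' Format: mapping linker name -> `{span: <A>, tolerance: <A>}` (or a
#' bare number, taken as the span with the default tolerance).
#' @param path YAML file.
#' @return List of [linker_spec()] objects.
#' @export
read_linker_table <- function(path) {
  y <- yaml::read_yaml(path)
  lapply(names(y), function(nm) {
    v <- y[[nm]]
    if (is.list(v)) {
      linker_spec(nm, span = v$span,
                  tolerance = if (!is.null(v$tolerance)) v$tolerance else 3)
    } else linker_spec(nm, span = v)
  })
}

#' Cbeta-Cbeta distance between two residues
#'
#' The Cbeta-Cbeta distance is the standard proxy for whether cysteines
#' engineered at two positions can be bridged by a thiol cross-linker;
#' it is measured on the wild-type side chains since the beta carbon is
#' unchanged by mutation to cysteine.  Glycine has no Cbeta: by default
#' such sites are rejected with an informative error; with
#' `virtual_gly = TRUE` an ideal tetrahedral Cbeta is reconstructed from
#' the N, CA and C positions.
#'
#' @param s a [fil_structure()].
#' @param site1,site2 each a list/vector `c(chain, resno)` (chain id and
#'   author residue number).
#' @param virtual_gly reconstruct a virtual Cbeta for glycine.
#' @return Distance in Angstrom.
#' @export
cbeta_distance <- function(s, site1, site2, virtual_gly = FALSE) {
  p1 <- cbeta_coord(s, site1, virtual_gly)
  p2 <- cbeta_coord(s, site2, virtual_gly)
  sqrt(sum((p1 - p2)^2))
}

cbeta_coord <- function(s, site, virtual_gly = FALSE) {
  chain <- as.character(site[[1]])
  resno <- as.integer(site[[2]])
  sel <- select_atoms(s, chain = chain, resno = resno,
                      warn_empty = FALSE)
  if (!nrow(sel))
    stop("cbeta_coord: no residue ", resno, " in chain ", chain)
  cb <- sel[sel$elety == "CB", , drop = FALSE]
  if (nrow(cb)) return(as.numeric(coords(cb)[1, ]))
  if (sel$resid[1] == "GLY" && !virtual_gly)
    stop("cbeta_coord: residue ", resno, " in chain ", chain,
         " is glycine (no CB); set virtual_gly = TRUE to reconstruct")
  if (!virtual_gly)
    stop("cbeta_coord: residue ", resno, " in chain ", chain,
         " has no CB atom")
  virtual_cbeta(sel)
}

# ideal tetrahedral CB from N, CA, C (bond 1.53 A)
virtual_cbeta <- function(sel) {
  get <- function(a) {
    r <- sel[sel$elety == a, , drop = FALSE]
    if (!nrow(r)) stop("virtual_cbeta: missing main-chain atom ", a)
    as.numeric(coords(r)[1, ])
  }
  n <- get("N"); ca <- get("CA"); cc <- get("C")
  b1 <- n - ca; b2 <- cc - ca
  b1 <- b1 / sqrt(sum(b1^2)); b2 <- b2 / sqrt(sum(b2^2))
  bis <- -(b1 + b2); bis <- bis / sqrt(sum(bis^2))
  perp <- c(b1[2] * b2[3] - b1[3] * b2[2],
            b1[3] * b2[1] - b1[1] * b2[3],
            b1[1] * b2[2] - b1[2] * b2[1])
  perp <- perp / sqrt(sum(perp^2))
  # tetrahedral branch direction: in-plane bisector tilted out of plane
  dir <- bis * cos(0.9509) + perp * sin(0.9509)  # 54.48 deg half-angle
  ca + 1.53 * dir / sqrt(sum(dir^2))
}

#' Scan interfaces for cysteine cross-link candidate pairs
#'
#' Enumerates inter-chain residue pairs across the interfaces of a
#' [filament graph][build_filament_graph()] with Cbeta-Cbeta distance at
#' most `max_distance`, annotating each with its interface class, the
#' compatible linkers, and whether the pair is a symmetry self-pair
#' (same residue number on both chains, the single-mutation designs
#' enabled by local C2 symmetry).  Glycines are skipped with a warning.
#'
#' @param s a [fil_structure()].
#' @param graph a `filament_graph`.
#' @param residues candidate residue numbers (default: all).
#' @param linkers list of [linker_spec()] objects (may be empty).
#' @param max_distance Angstrom.
#' @return Data frame of class `crosslink_candidates`, sorted by
#'   ascending distance (ties by residue numbers): columns `chain1`,
#'   `resno1`, `resid1`, `chain2`, `resno2`, `resid2`,
#'   `cbeta_distance`, `interface_label`, `symmetry_self_pair`,
#'   `compatible_linkers` (comma-separated), `shorter_than_span`
#'   (linkers whose span the pair undershoots by more than the
#'   tolerance), `background_min_distance` (NA until
#'   [background_check()]).
#' @export
scan_crosslink_pairs <- function(s, graph, residues = NULL,
                                 linkers = list(), max_distance = 12) {
  stopifnot(inherits(graph, "filament_graph"))
  if (inherits(linkers, "linker_spec")) linkers <- list(linkers)
  rows <- list()
  skipped_gly <- 0L
  for (k in seq_len(nrow(graph$edges))) {
    e <- graph$edges[k, ]
    cb1 <- chain_cbetas(s, e$chain1, residues)
    cb2 <- chain_cbetas(s, e$chain2, residues)
    skipped_gly <- skipped_gly + attr(cb1, "n_gly") + attr(cb2, "n_gly")
    if (!nrow(cb1) || !nrow(cb2)) next
    x1 <- coords(cb1); x2 <- coords(cb2)
    d2 <- outer(rowSums(x1^2), rowSums(x2^2), "+") - 2 * tcrossprod(x1, x2)
    hit <- which(d2 <= max_distance^2, arr.ind = TRUE)
    if (!nrow(hit)) next
    rows[[length(rows) + 1L]] <- data.frame(
      chain1 = e$chain1, resno1 = cb1$resno[hit[, 1]],
      resid1 = cb1$resid[hit[, 1]],
      chain2 = e$chain2, resno2 = cb2$resno[hit[, 2]],
      resid2 = cb2$resid[hit[, 2]],
      cbeta_distance = sqrt(pmax(d2[hit], 0)),
      interface_label = e$label)
  }
  if (!length(rows)) {
    warning("scan_crosslink_pairs: no candidate pairs within ",
            max_distance, " A")
    out <- data.frame(chain1 = character(), resno1 = integer(),
                      resid1 = character(), chain2 = character(),
                      resno2 = integer(), resid2 = character(),
                      cbeta_distance = numeric(),
                      interface_label = character(),
                      symmetry_self_pair = logical(),
                      compatible_linkers = character(),
                      shorter_than_span = character(),
                      background_min_distance = numeric())
    class(out) <- c("crosslink_candidates", "data.frame")
    return(out)
  }
  if (skipped_gly > 0)
    warning("scan_crosslink_pairs: skipped ", skipped_gly,
            " glycine residues (no CB)", call. = FALSE)
  out <- do.call(rbind, rows)
  out$symmetry_self_pair <- out$resno1 == out$resno2
  comp <- vapply(out$cbeta_distance, function(d) {
    ok <- vapply(linkers, function(l) d <= l$span + l$tolerance,
                 logical(1))
    paste(vapply(linkers[ok], `[[`, character(1), "name"),
          collapse = ",")
  }, character(1))
  short <- vapply(out$cbeta_distance, function(d) {
    ok <- vapply(linkers, function(l) d < l$span - l$tolerance,
                 logical(1))
    paste(vapply(linkers[ok], `[[`, character(1), "name"),
          collapse = ",")
  }, character(1))
  out$compatible_linkers <- comp
  out$shorter_than_span <- short
  out$background_min_distance <- NA_real_
  out <- out[order(out$cbeta_distance, out$resno1, out$resno2), ]
  rownames(out) <- NULL
  class(out) <- c("crosslink_candidates", "data.frame")
  out
}

chain_cbetas <- function(s, chain, residues = NULL) {
  sel <- select_atoms(s, chain = chain, resno = residues, elety = "CB",
                      warn_empty = FALSE)
  all_res <- select_atoms(s, chain = chain, resno = residues,
                          elety = "CA", warn_empty = FALSE)
  n_gly <- sum(all_res$resid == "GLY")
  attr(sel, "n_gly") <- n_gly
  sel
}

#' Background reactivity against endogenous cysteines
#'
#' For every candidate site, finds the minimum inter-chain Cbeta-Cbeta
#' distance to any endogenous-cysteine position across any interface of
#' the graph.  Designs whose background distance falls below
#' `warn_threshold` are flagged as possible off-target cross-linkers.
#'
#' @param candidates a `crosslink_candidates` table.
#' @param s a [fil_structure()].
#' @param graph the `filament_graph` used for the scan.
#' @param endogenous_cys residue numbers of native cysteines; when empty
#'   the background distance is infinite.
#' @param warn_threshold Angstrom (default 12).
#' @return `candidates` with `background_min_distance` filled and a
#'   logical `background_flag` column added.
#' @export
background_check <- function(candidates, s, graph, endogenous_cys,
                             warn_threshold = 12) {
  stopifnot(inherits(candidates, "crosslink_candidates"))
  if (!length(endogenous_cys)) {
    candidates$background_min_distance <- Inf
    candidates$background_flag <- FALSE
    return(candidates)
  }
  pairs <- unique(rbind(
    data.frame(chain = candidates$chain1, resno = candidates$resno1),
    data.frame(chain = candidates$chain2, resno = candidates$resno2)))
  bg <- vapply(seq_len(nrow(pairs)), function(i) {
    site_background(s, graph, pairs$chain[i], pairs$resno[i],
                    endogenous_cys)
  }, numeric(1))
  key <- paste(pairs$chain, pairs$resno)
  b1 <- bg[match(paste(candidates$chain1, candidates$resno1), key)]
  b2 <- bg[match(paste(candidates$chain2, candidates$resno2), key)]
  candidates$background_min_distance <- pmin(b1, b2)
  candidates$background_flag <-
    candidates$background_min_distance < warn_threshold
  candidates
}

# min cross-chain CB distance from (chain, resno) to endogenous
# cysteines on chains interfacing with `chain`
site_background <- function(s, graph, chain, resno, endogenous_cys) {
  e <- graph$edges
  partners <- unique(c(e$chain2[e$chain1 == chain],
                       e$chain1[e$chain2 == chain]))
  if (!length(partners)) return(Inf)
  p0 <- tryCatch(cbeta_coord(s, list(chain, resno)),
                 error = function(err) NULL)
  if (is.null(p0)) return(Inf)
  dmin <- Inf
  for (pc in partners) {
    cb <- select_atoms(s, chain = pc, resno = endogenous_cys,
                       elety = "CB", warn_empty = FALSE)
    if (!nrow(cb)) next
    d <- sqrt(rowSums(sweep(coords(cb), 2, p0)^2))
    dmin <- min(dmin, d)
  }
  dmin
}

#' Symmetry self-pairs at a C2 interface
#'
#' Because the two chains of a locally C2-symmetric interface are
#' equivalent, a *single* cysteine mutation produces a cross-linkable
#' pair with its own symmetry mate.  This helper restricts the scan to
#' same-residue-number cross-chain pairs at one interface.  When the
#' interface lacks C2 symmetry a warning is emitted and the pairs are
#' still computed.
#'
#' @param s a [fil_structure()].
#' @param iface an `interface_contact` or 2-vector of chain ids.
#' @param c2 optional `c2_assessment` from [detect_c2()] (computed if
#'   missing).
#' @param residues candidate residue numbers (default: all).
#' @param max_distance Angstrom.
#' @return Data frame: `resno`, `resid`, `cbeta_distance`, sorted by
#'   distance.
#' @export
c2_self_pairs <- function(s, iface, c2 = NULL, residues = NULL,
                          max_distance = Inf) {
  ch <- if (inherits(iface, "interface_contact")) iface$chains else iface
  if (is.null(c2)) c2 <- detect_c2(s, ch)
  if (!c2$has_c2)
    warning("c2_self_pairs: interface ", ch[1], "-", ch[2],
            " lacks C2 symmetry; self-pairs computed anyway")
  cb1 <- select_atoms(s, chain = ch[1], resno = residues, elety = "CB",
                      warn_empty = FALSE)
  cb2 <- select_atoms(s, chain = ch[2], resno = residues, elety = "CB",
                      warn_empty = FALSE)
  common <- intersect(cb1$resno, cb2$resno)
  if (!length(common))
    return(data.frame(resno = integer(), resid = character(),
                      cbeta_distance = numeric()))
  i1 <- match(common, cb1$resno)
  i2 <- match(common, cb2$resno)
  d <- sqrt(rowSums((coords(cb1)[i1, , drop = FALSE] -
                     coords(cb2)[i2, , drop = FALSE])^2))
  out <- data.frame(resno = common, resid = cb1$resid[i1],
                    cbeta_distance = d)
  out <- out[out$cbeta_distance <= max_distance, , drop = FALSE]
  out <- out[order(out$cbeta_distance, out$resno), ]
  rownames(out) <- NULL
  out
}
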