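#' Atomic structure container
#'
#' protofil represents an atomic model as a flat atom table (one row per
#' atom) plus metadata, the same layout used by crystallographic atom_site
#' records: columns `chain`, `resno` (author numbering), `insert`,
#' `resid` (3-letter residue code), `elety` (atom name), `elesy`
#' (element), `x`, `y`, `z` (Angstrom), `o` (occupancy), `alt`
#' (alternate-location tag, "" if none) and `polymer` (logical).
#'
#' @param atoms data frame with the columns listed above.
#' @param id accession or file stem.
#' @param symmetry_ops optional list of [rigid_transform()] operators
#'   (e.g. materialised crystal-symmetry operators).
#' @return An object of class `fil_structure`.
#' @export
fil_structure <- function(atoms, id = "structure", symmetry_ops = NULL) {
  need <- c("chain", "resno", "insert", "resid", "elety", "elesy",
            "x", "y", "z", "o", "alt", "polymer")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols))
    stop("fil_structure: atoms table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  atoms <- as.data.frame(atoms)[, need]
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("fil_structure: non-finite coordinates")
  if (any(atoms$o < 0 | atoms$o > 1, na.rm = TRUE))
    stop("fil_structure: occupancy outside [0, 1]")
  dup <- duplicated(atoms[, c("chain", "resno", "insert", "elety")])
  if (any(dup))
    stop("fil_structure: duplicate atom after altloc resolution, e.g. ",
         with(atoms[dup, ][1, ], paste(chain, resno, elety)))
  if (!is.null(symmetry_ops)) {
    stopifnot(is.list(symmetry_ops),
              all(vapply(symmetry_ops, is_rigid_transform, logical(1))))
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, id = id, symmetry_ops = symmetry_ops),
            class = "fil_structure")
}

#' @export
print.fil_structure <- function(x, ...) {
  ch <- chain_ids(x)
  pch <- polymer_chains(x)
  cat(sprintf("fil_structure '%s': %d atoms, %d chains (%d polymer)\n",
              x$id, nrow(x$atoms), length(ch), length(pch)))
  cat("  chains:", paste(utils::head(ch, 20), collapse = " "),
      if (length(ch) > 20) "..." else "", "\n")
  if (!is.null(x$symmetry_ops))
    cat("  symmetry operators:", length(x$symmetry_ops), "\n")
  invisible(x)
}

#' @rdname fil_structure
#' @param x a `fil_structure`.
#' @export
chain_ids <- function(x) unique(x$atoms$chain)

#' Polymer chains of a structure
#'
#' @param x a `fil_structure`.
#' @param min_residues chains with fewer residues are dropped; use this
#'   to exclude short peptide chains (e.g. peptides deposited as poly-Ala)
#'   from filament topology while keeping them in the model.
#' @return Character vector of chain identifiers.
#' @export
polymer_chains <- function(x, min_residues = 1) {
  a <- x$atoms[x$atoms$polymer, , drop = FALSE]
  if (!nrow(a)) return(character())
  nres <- tapply(paste(a$resno, a$insert), a$chain,
                 function(z) length(unique(z)))
  names(nres)[nres >= min_residues]
}

standard_aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL", "MSE", "UNK")
water_resid <- c("HOH", "WAT", "DOD", "H2O")

#' Read an atomic coordinate model
#'
#' Reads PDB or mmCIF through bio3d and canonicalises the model:
#' hydrogens and waters are dropped, alternate locations are resolved by
#' keeping the highest-occupancy copy (ties broken by the
#' lexicographically first altloc tag), and chains of standard amino
#' acids are flagged as polymer.  Biological-assembly operators found in
#' PDB REMARK 350 records are retained as `symmetry_ops`; operators can
#' also be supplied from a plain-text file via [read_operators()].
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return A [fil_structure()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_structure: no such file: ", path)
  if (file.size(path) == 0)
    stop("read_structure: parse error: empty file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     pdb = , ent = "pdb",
                     cif = , mmcif = "mmcif",
                     stop("read_structure: cannot infer format from ",
                          "extension '", ext, "'; pass format="))
  }
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE,
                                         rm.alt = FALSE)
    else bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE),
    error = function(e) stop("read_structure: parse error in '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || !nrow(at))
    stop("read_structure: parse error: no atom records in ", path)
  atoms <- data.frame(
    chain = ifelse(is.na(at$chain), "", as.character(at$chain)),
    resno = as.integer(at$resno),
    insert = ifelse(is.na(at$insert), "", as.character(at$insert)),
    resid = as.character(at$resid),
    elety = as.character(at$elety),
    elesy = guess_element(at$elesy, at$elety),
    x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1, pmin(1, pmax(0, at$o))),
    alt = ifelse(is.na(at$alt), "", as.character(at$alt)),
    stringsAsFactors = FALSE)
  atoms <- atoms[atoms$elesy != "H" & atoms$elesy != "D", , drop = FALSE]
  atoms <- atoms[!(atoms$resid %in% water_resid), , drop = FALSE]
  if (!nrow(atoms))
    stop("read_structure: parse error: no heavy atoms left in ", path)
  atoms <- resolve_altlocs(atoms)
  atoms$polymer <- atoms$resid %in% standard_aa
  ops <- remark350_operators(pdb)
  fil_structure(atoms, id = tools::file_path_sans_ext(basename(path)),
                symmetry_ops = ops)
}

guess_element <- function(elesy, elety) {
  out <- toupper(ifelse(is.na(elesy) | elesy == "", NA, elesy))
  miss <- is.na(out)
  if (any(miss)) {
    # strip digits/primes, take leading letters; two-letter only for
    # common heteroatoms
    nm <- gsub("[^A-Za-z].*$", "", gsub("^[0-9']+", "", elety[miss]))
    first <- toupper(substr(nm, 1, 1))
    out[miss] <- ifelse(first %in% c("C", "N", "O", "S", "P", "H"),
                        first, toupper(substr(nm, 1, 2)))
  }
  out
}

resolve_altlocs <- function(atoms) {
  alt <- ifelse(atoms$alt %in% c("", " ", "."), "", atoms$alt)
  atoms$alt <- alt
  if (!any(alt != "")) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety,
               sep = "\r")
  # order: highest occupancy first, then lexicographic altloc
  ord <- order(key, -atoms$o, atoms$alt)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms[order(match(atoms$chain, unique(atoms$chain)), atoms$resno,
              atoms$insert), , drop = FALSE]
}

remark350_operators <- function(pdb) {
  bm <- tryCatch(pdb$remark$biomat, error = function(e) NULL)
  if (is.null(bm) || is.null(bm$mat)) return(NULL)
  mats <- unlist(bm$mat, recursive = FALSE)
  ops <- lapply(mats, function(m) {
    m <- as.matrix(m)
    if (!all(dim(m) == c(3, 4))) return(NULL)
    tryCatch(rigid_transform(m[, 1:3], m[, 4]), error = function(e) NULL)
  })
  ops <- Filter(Negate(is.null), ops)
  if (length(ops)) ops else NULL
}

#' Select atoms from a structure
#'
#' Returns the matching atom rows ordered by (chain, residue number,
#' canonical atom order N, CA, C, O, CB, then alphabetical).  The result
#' is a deterministic function of the structure and the selection.
#'
#' @param s a [fil_structure()].
#' @param chain,resno,elety,resid optional filters (vectors; `NULL`
#'   means no restriction on that field).
#' @param polymer_only drop non-polymer (ligand) atoms.
#' @param warn_empty warn when the selection matches nothing.
#' @return A data frame of class `atom_selection` with provenance
#'   columns (`chain`, `resno`, `insert`, `resid`, `elety`) and
#'   coordinates; see [coords()].
#' @examples
#' # main-chain atoms of residues 82-160 of chain A:
#' # select_atoms(s, chain = "A", resno = 82:160, elety = c("N","CA","C"))
#' @export
select_atoms <- function(s, chain = NULL, resno = NULL, elety = NULL,
                         resid = NULL, polymer_only = TRUE,
                         warn_empty = TRUE) {
  stopifnot(inherits(s, "fil_structure"))
  a <- s$atoms
  if (polymer_only) a <- a[a$polymer, , drop = FALSE]
  if (!is.null(chain)) {
    missing_ch <- setdiff(chain, s$atoms$chain)
    if (length(missing_ch))
      stop("select_atoms: no such chain(s): ",
           paste(missing_ch, collapse = ", "))
    a <- a[a$chain %in% chain, , drop = FALSE]
  }
  if (!is.null(resno)) a <- a[a$resno %in% resno, , drop = FALSE]
  if (!is.null(resid)) a <- a[a$resid %in% resid, , drop = FALSE]
  if (!is.null(elety)) a <- a[a$elety %in% elety, , drop = FALSE]
  if (!nrow(a) && warn_empty)
    warning("select_atoms: empty selection", call. = FALSE)
  a <- a[order(match(a$chain, unique(s$atoms$chain)), a$resno, a$insert,
               atom_rank(a$elety)), , drop = FALSE]
  rownames(a) <- NULL
  class(a) <- c("atom_selection", "data.frame")
  a
}

atom_rank <- function(elety) {
  canon <- c("N", "CA", "C", "O", "CB")
  r <- match(elety, canon)
  ifelse(is.na(r), length(canon) + as.integer(factor(elety)), r)
}

#' Coordinate matrix of a selection or structure
#' @param x an `atom_selection`, `fil_structure`, matrix or data frame.
#' @return n x 3 numeric matrix (Angstrom).
#' @export
coords <- function(x) {
  if (inherits(x, "fil_structure")) x <- x$atoms
  as_coord_matrix(x)
}

#' Apply a rigid transform to a structure or coordinate set
#'
#' All pairwise distances are preserved (rigid motion).  Improper
#' rotations are rejected by the [rigid_transform()] constructor.
#'
#' @param x a [fil_structure()], `atom_selection`, data frame or n x 3
#'   matrix.
#' @param t a [rigid_transform()].
#' @return Same shape as `x`, with transformed coordinates.
#' @export
apply_transform <- function(x, t) {
  stopifnot(is_rigid_transform(t))
  if (inherits(x, "fil_structure")) {
    x$atoms[, c("x", "y", "z")] <- rt_apply(t, coords(x$atoms))
    return(x)
  }
  if (is.data.frame(x)) {
    x[, c("x", "y", "z")] <- rt_apply(t, as_coord_matrix(x))
    return(x)
  }
  rt_apply(t, x)
}

#' Expand an assembly by symmetry operators
#'
#' Generates transformed copies of a structure's chains.  For each
#' operator `j` and copy index `k` in `1:copies`, the k-th power of
#' operator `j` is applied to the source chains, so a single screw
#' operator with `copies = n` extends a protomer into an `n + 1`-subunit
#' helix.  Generated chains receive deterministic derived identifiers
#' `<source>.<operator>.<copy>` (or fresh single-character ids with
#' `chain_ids = "letters"`, required for PDB output).
#'
#' @param s a [fil_structure()].
#' @param ops list of [rigid_transform()] operators (or a single one).
#' @param copies number of successive applications of each operator.
#' @param chains source chains (default: all).
#' @param chain_ids `"derived"` or `"letters"`.
#' @return A [fil_structure()] containing the original plus generated
#'   chains; the mapping from new to source chains is in
#'   `attr(, "chain_map")`.
#' @export
expand_assembly <- function(s, ops, copies = 1, chains = NULL,
                            chain_ids = c("derived", "letters")) {
  stopifnot(inherits(s, "fil_structure"), copies >= 1)
  chain_ids <- match.arg(chain_ids)
  if (is_rigid_transform(ops)) ops <- list(ops)
  stopifnot(length(ops) >= 1,
            all(vapply(ops, is_rigid_transform, logical(1))))
  if (is.null(chains)) chains <- chain_ids(s)
  src <- s$atoms[s$atoms$chain %in% chains, , drop = FALSE]
  pieces <- list(s$atoms)
  map <- data.frame(chain = chain_ids(s), source = chain_ids(s),
                    operator = 0L, copy = 0L)
  pool <- setdiff(c(LETTERS, letters, as.character(0:9)), chain_ids(s))
  for (j in seq_along(ops)) {
    tj <- rt_identity()
    for (k in seq_len(copies)) {
      tj <- rt_compose(ops[[j]], tj)
      blk <- src
      blk[, c("x", "y", "z")] <- rt_apply(tj, as_coord_matrix(blk))
      for (ch in unique(blk$chain)) {
        new_id <- if (chain_ids == "derived") {
          paste(ch, j, k, sep = ".")
        } else {
          if (!length(pool))
            stop("expand_assembly: ran out of single-character chain ids")
          id <- pool[1]; pool <- pool[-1]; id
        }
        if (new_id %in% map$chain) {          # collision: rename, log
          new_id2 <- make.unique(c(map$chain, new_id))[length(map$chain) + 1]
          message("expand_assembly: chain id collision, renaming ",
                  new_id, " -> ", new_id2)
          new_id <- new_id2
        }
        blk$chain[blk$chain == ch] <- new_id
        map <- rbind(map, data.frame(chain = new_id, source = ch,
                                     operator = j, copy = k))
      }
      pieces[[length(pieces) + 1L]] <- blk
    }
  }
  out <- fil_structure(do.call(rbind, pieces), id = s$id,
                       symmetry_ops = s$symmetry_ops)
  attr(out, "chain_map") <- map
  out
}

#' Write a structure to PDB or mmCIF
#'
#' PDB output stores coordinates at 3 decimals (1e-3 Angstrom); the
#' mmCIF writer uses 5 decimals.  PDB format cannot represent more than
#' 62 chains or multi-character chain identifiers; such structures must
#' be written as mmCIF (or re-labelled, see [expand_assembly()]).
#'
#' @param s a [fil_structure()].
#' @param path output file path.
#' @param format `"pdb"` or `"mmcif"` (default from extension).
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path, format = c("auto", "pdb", "mmcif")) {
  stopifnot(inherits(s, "fil_structure"), nrow(s$atoms) > 0)
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", cif = , mmcif = "mmcif",
                     stop("write_structure: cannot infer format from '",
                          ext, "'"))
  }
  a <- s$atoms
  if (format == "pdb") {
    ch <- unique(a$chain)
    if (length(ch) > 62 || any(nchar(ch) > 1))
      stop("write_structure: ", length(ch), " chains / multi-character ",
           "chain ids cannot be written as PDB; use mmCIF")
    n <- nrow(a)
    bio3d::write.pdb(file = path,
                     xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                     type = ifelse(a$polymer, "ATOM", "HETATM"),
                     resno = a$resno, resid = a$resid, chain = a$chain,
                     eleno = seq_len(n),
                     insert = ifelse(a$insert == "", NA, a$insert),
                     elety = a$elety, o = a$o, b = rep(0, n),
                     elesy = a$elesy)
  } else {
    write_mmcif(s, path)
  }
  invisible(path)
}

# minimal mmCIF atom_site writer (coordinates at 1e-5 A); no installed R
# package writes mmCIF
write_mmcif <- function(s, path) {
  a <- s$atoms
  lines <- c(
    paste0("data_", gsub("[^A-Za-z0-9_-]", "_", s$id)),
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num")
  rows <- sprintf(
    "%s %d %s %s . %s %s 1 %d %s %.5f %.5f %.5f %.2f %.2f ? %d %s %s %s 1",
    ifelse(a$polymer, "ATOM", "HETATM"),
    seq_len(nrow(a)), a$elesy, a$elety, a$resid, a$chain, a$resno,
    ifelse(a$insert == "", "?", a$insert),
    a$x, a$y, a$z, a$o, 0, a$resno, a$resid, a$chain, a$elety)
  writeLines(c(lines, rows, "#"), path)
  invisible(path)
}

#' Read and write rigid-transform operator files
#'
#' Operators are stored as plain-text 3x4 matrix blocks (rotation | t),
#' one operator per block, blocks separated by blank lines; `#` starts a
#' comment.  This is the dialect used for materialised crystal-symmetry
#' operators throughout protofil.
#'
#' @param path file path.
#' @return `read_operators`: list of [rigid_transform()].
#' @export
read_operators <- function(path) {
  if (!file.exists(path)) stop("read_operators: no such file: ", path)
  ln <- trimws(readLines(path))
  ln <- sub("#.*$", "", ln)
  ln <- trimws(ln)
  blocks <- split(ln[ln != ""], cumsum(ln == "")[ln != ""])
  ops <- lapply(blocks, function(b) {
    if (length(b) != 3)
      stop("read_operators: operator block with ", length(b),
           " rows (need 3) in ", path)
    m <- do.call(rbind, lapply(b, function(r)
      as.numeric(strsplit(r, "[ \t,]+")[[1]])))
    if (ncol(m) != 4)
      stop("read_operators: rows must hold 4 numbers in ", path)
    rigid_transform(m[, 1:3], m[, 4])
  })
  unname(ops)
}

#' @rdname read_operators
#' @param ops list of [rigid_transform()] objects.
#' @export
write_operators <- function(ops, path) {
  if (is_rigid_transform(ops)) ops <- list(ops)
  txt <- unlist(lapply(ops, function(t) {
    m <- cbind(t$rotation, t$translation)
    c(apply(m, 1, function(r) paste(sprintf("%.9f", r), collapse = " ")),
      "")
  }))
  writeLines(txt, path)
  invisible(path)
}

#' Per-chain centroids
#'
#' Centroid (unweighted mean position) of the selected atoms of each
#' chain, the reference points used for curvature fitting and diameter
#' measurements.
#'
#' @param s a [fil_structure()].
#' @param chains chains to include (default: all polymer chains).
#' @param elety optional atom-name restriction (default: all heavy atoms).
#' @return Matrix with one row per chain (rownames = chain ids).
#' @export
chain_centroids <- function(s, chains = NULL, elety = NULL) {
  if (is.null(chains)) chains <- polymer_chains(s)
  out <- t(vapply(chains, function(ch) {
    colMeans(coords(select_atoms(s, chain = ch, elety = elety,
                                 warn_empty = FALSE)))
  }, numeric(3)))
  colnames(out) <- c("x", "y", "z")
  out
}
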