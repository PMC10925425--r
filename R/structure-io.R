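#' Read a macromolecular structure from PDB or mmCIF
#'
#' Parses a coordinate file into a `structure_model`: a flat atom table
#' (chain, residue number, insertion code, residue name, atom name, element,
#' position, occupancy, altloc) plus bookkeeping. Parsing is delegated to
#' \pkg{bio3d}; all atoms of the requested model are kept, including
#' alternate locations and waters.
#'
#' @param path Path to a PDB or mmCIF file.
#' @param format `"auto"` (by extension), `"pdb"`, or `"mmcif"`.
#' @param model Model number for multi-model files (default 1).
#' @param source_id Identifier stored with the model (defaults to the file
#'   base name, e.g. a PDB accession).
#' @return A `structure_model` object: `list(atoms = <data.frame>, model_id,
#'   source_id)`. The atom table carries one row per atom with columns
#'   `eleno, chain, resno, insert, resid, elety, element, x, y, z, o, alt,
#'   is_hetero, is_water`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           model = 1L, source_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop2("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    else bio3d::read.cif(path, verbose = FALSE),
    error = function(e) stop2("could not parse '", path, "' as ", format, ": ",
                              conditionMessage(e))
  )
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0L)
    stop2("empty model in ", path)
  at <- pdb$atom
  nmod <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  if (model < 1L || model > nmod)
    stop2("model ", model, " requested but file holds ", nmod, " model(s)")
  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[model, ] else as.numeric(pdb$xyz)
  co <- matrix(xyz, ncol = 3, byrow = TRUE)

  element <- at$elesy
  if (is.null(element)) element <- rep(NA_character_, nrow(at))
  element <- toupper(trimws(ifelse(is.na(element) | element == "",
                                   element_from_name(at$elety), element)))
  atoms <- data.frame(
    eleno  = seq_len(nrow(at)),
    chain  = ifelse(is.na(at$chain), "", at$chain),
    resno  = as.integer(at$resno),
    insert = ifelse(is.na(at$insert), "", at$insert),
    resid  = toupper(at$resid),
    elety  = at$elety,
    element = element,
    x = co[, 1], y = co[, 2], z = co[, 3],
    o = ifelse(is.na(at$o), 1, at$o),
    alt = ifelse(is.na(at$alt), "", at$alt),
    stringsAsFactors = FALSE
  )
  atoms$is_water  <- atoms$resid %in% WATER_NAMES
  atoms$is_hetero <- at$type == "HETATM" | atoms$is_water
  if (any(!is.finite(co))) stop2("non-finite coordinates in ", path)
  new_structure_model(atoms, model_id = as.integer(model),
                      source_id = source_id %||%
                        toupper(tools::file_path_sans_ext(basename(path))))
}

#' @keywords internal
new_structure_model <- function(atoms, model_id = 1L, source_id = "model") {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0)
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z))))
    stop2("atom positions must be finite")
  structure(list(atoms = atoms, model_id = model_id, source_id = source_id),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model", x$source_id, "(model", x$model_id, "):",
      nrow(x$atoms), "atoms,", length(unique(x$atoms$chain)), "chain(s),",
      sum(x$atoms$is_water), "water atom(s)\n")
  invisible(x)
}

#' Write a structure_model to a PDB file
#'
#' Used mainly to materialise synthetic fixtures in the exact dialect
#' [read_structure()] consumes. Coordinates are written at PDB precision
#' (1e-3 Angstrom).
#'
#' @param model A `structure_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  a <- model$atoms
  bio3d::write.pdb(
    file = path,
    xyz  = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = ifelse(a$is_hetero, "HETATM", "ATOM"),
    resno = a$resno, resid = a$resid, eleno = a$eleno,
    elety = a$elety, chain = a$chain,
    insert = ifelse(a$insert == "", NA, a$insert),
    alt = ifelse(a$alt == "", NA, a$alt),
    o = a$o, b = rep(0, nrow(a)), elesy = a$element
  )
  invisible(path)
}

#' Select atoms by residue name, chain, residue number or atom name
#'
#' All supplied filters are combined with AND; `NULL` filters are ignored.
#' An empty result is valid and returned as a zero-row atom table.
#'
#' @param model A `structure_model`.
#' @param resid Character vector of 3-letter residue names.
#' @param chain Character vector of chain identifiers.
#' @param resno Integer vector of residue numbers.
#' @param elety Character vector of atom names.
#' @param water `TRUE`/`FALSE` to keep only waters / only non-waters.
#' @param hetero `TRUE`/`FALSE` to keep only HETATM / only ATOM records.
#' @return A data.frame of matching atom records.
#' @export
select_atoms <- function(model, resid = NULL, chain = NULL, resno = NULL,
                         elety = NULL, water = NULL, hetero = NULL) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(resid)) {
    if (!is.character(resid)) stop2("'resid' must be character")
    keep <- keep & a$resid %in% toupper(resid)
  }
  if (!is.null(chain)) {
    if (!is.character(chain)) stop2("'chain' must be character")
    keep <- keep & a$chain %in% chain
  }
  if (!is.null(resno)) {
    if (!is.numeric(resno)) stop2("'resno' must be numeric")
    keep <- keep & a$resno %in% as.integer(resno)
  }
  if (!is.null(elety)) {
    if (!is.character(elety)) stop2("'elety' must be character")
    keep <- keep & a$elety %in% elety
  }
  if (!is.null(water))  keep <- keep & (a$is_water == water)
  if (!is.null(hetero)) keep <- keep & (a$is_hetero == hetero)
  a[keep, , drop = FALSE]
}

#' Resolve alternate locations to a single conformer
#'
#' Keeps, for each (chain, residue, insertion, atom name), the altloc with the
#' highest occupancy; ties are broken by altloc label order so the result is
#' deterministic.
#'
#' @param atoms An atom table (as in `model$atoms`).
#' @return The atom table with one row per unique atom.
#' @export
resolve_altlocs <- function(atoms) {
  if (nrow(atoms) == 0) return(atoms)
  key <- paste(residue_key(atoms), atoms$elety, sep = "|")
  ord <- order(key, -atoms$o, atoms$alt)
  atoms <- atoms[ord, , drop = FALSE]
  atoms[!duplicated(paste(residue_key(atoms), atoms$elety, sep = "|")), ,
        drop = FALSE]
}

#' Residues with any heavy atom within a cutoff of a center selection
#'
#' A residue is included iff the minimum heavy-atom distance between any of
#' its atoms and any center atom is at most `cutoff`. Residues contributing
#' center atoms are excluded; hydrogens are excluded by default on both sides
#' (deposited structures rarely carry them).
#'
#' @param model A `structure_model`.
#' @param center_atoms Atom table of center atoms (e.g. a ligand selection).
#' @param cutoff Distance cutoff in Angstrom (> 0).
#' @param heavy_only Exclude hydrogens/deuteriums (default `TRUE`).
#' @return data.frame with one row per shell residue: `chain, resno, insert,
#'   resid, min_dist`, sorted by distance.
#' @export
residues_within <- function(model, center_atoms, cutoff, heavy_only = TRUE) {
  stopifnot(inherits(model, "structure_model"))
  if (is.null(center_atoms) || nrow(center_atoms) == 0)
    stop2("center_atoms must be non-empty")
  if (!is.numeric(cutoff) || cutoff <= 0) stop2("cutoff must be > 0")
  a <- model$atoms
  if (heavy_only) {
    a <- a[is_heavy(a), , drop = FALSE]
    center_atoms <- center_atoms[is_heavy(center_atoms), , drop = FALSE]
    if (nrow(center_atoms) == 0) stop2("center_atoms holds no heavy atoms")
  }
  center_res <- unique(residue_key(center_atoms))
  a <- a[!(residue_key(a) %in% center_res), , drop = FALSE]
  empty <- data.frame(chain = character(), resno = integer(),
                      insert = character(), resid = character(),
                      min_dist = numeric(), stringsAsFactors = FALSE)
  if (nrow(a) == 0) return(empty)
  d <- cross_dist(as.matrix(a[, c("x", "y", "z")]),
                  as.matrix(center_atoms[, c("x", "y", "z")]))
  mind <- apply(d, 1, min)
  hit <- mind <= cutoff
  if (!any(hit)) return(empty)
  a <- a[hit, , drop = FALSE]
  mind <- mind[hit]
  key <- residue_key(a)
  agg <- tapply(mind, key, min)
  first <- a[!duplicated(key), , drop = FALSE]
  out <- data.frame(chain = first$chain, resno = first$resno,
                    insert = first$insert, resid = first$resid,
                    min_dist = as.numeric(agg[residue_key(first)]),
                    stringsAsFactors = FALSE)
  out[order(out$min_dist), , drop = FALSE]
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Superposes `mobile` onto `reference` over the supplied index pairing using
#' the SVD solution constrained to a proper rotation (det = +1), and reports
#' the RMSD over the paired atoms after the transform.
#'
#' @param mobile,reference Numeric matrices (n x 3) of coordinates, or atom
#'   tables with `x,y,z` columns.
#' @param pairing Two-column integer matrix of (mobile, reference) row
#'   indices; defaults to the identity pairing.
#' @return list with `rotation` (3x3, det +1), `translation` (length 3, so
#'   that `transformed = mobile %*% t(rotation) + translation`), `rmsd`
#'   (Angstrom) and `transformed` coordinates of the full mobile set.
#' @export
superpose <- function(mobile, reference, pairing = NULL) {
  as_xyz <- function(m) {
    if (is.data.frame(m)) m <- as.matrix(m[, c("x", "y", "z")])
    matrix(as.numeric(m), ncol = 3)
  }
  mob <- as_xyz(mobile); ref <- as_xyz(reference)
  if (is.null(pairing)) {
    if (nrow(mob) != nrow(ref))
      stop2("mobile and reference differ in size; supply 'pairing'")
    pairing <- cbind(seq_len(nrow(mob)), seq_len(nrow(ref)))
  }
  pairing <- matrix(as.integer(pairing), ncol = 2)
  if (nrow(pairing) < 3) stop2("at least 3 atom pairs required")
  pm <- mob[pairing[, 1], , drop = FALSE]
  pr <- ref[pairing[, 2], , drop = FALSE]
  cm <- colMeans(pm); cr <- colMeans(pr)
  A <- sweep(pm, 2, cm); B <- sweep(pr, 2, cr)
  ## collinearity check: the paired set must span a plane
  if (svd(A)$d[2] < 1e-8 || svd(B)$d[2] < 1e-8)
    stop2("degenerate (collinear) atom pairing; superposition undefined")
  H <- crossprod(A, B)                 # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  translation <- as.numeric(cr - R %*% cm)
  fit_pairs <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((fit_pairs - B)^2)))
  transformed <- mob %*% t(R) + matrix(translation, nrow(mob), 3, byrow = TRUE)
  list(rotation = R, translation = translation, rmsd = rmsd,
       transformed = transformed)
}
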