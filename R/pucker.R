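#' Signed torsion angle of four ordered points
#'
#' Standard signed dihedral: the angle between the plane of (p1, p2, p3) and
#' the plane of (p2, p3, p4), measured about the p2-p3 axis, in degrees in
#' (-180, 180].
#'
#' @param p1,p2,p3,p4 Numeric length-3 position vectors (Angstrom).
#' @return Signed angle in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (vnorm(b1) < 1e-9 || vnorm(b2) < 1e-9 || vnorm(b3) < 1e-9)
    stop2("degenerate dihedral: coincident consecutive points")
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9)
    stop2("degenerate dihedral: collinear bond vectors")
  ## IUPAC sign: cis = 0, positive clockwise looking from p2 toward p3
  ang <- atan2(sum(vcross(n1, n2) * b2 / vnorm(b2)), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Default nicotinamide ring atom names
#'
#' Ring positions 1..6 for NADP/NADPH-style ligands (PDB chemical components
#' NAP, NDP and the covalent adducts derived from them): position 1 is the
#' ring nitrogen N1N and position 4 the opposite carbon C4N, where the
#' covalent bond forms in the adducts.
#'
#' @return Character vector of six atom names in ring-position order.
#' @export
nicotinamide_ring_names <- function() c("N1N", "C2N", "C3N", "C4N", "C5N", "C6N")

#' Assign the six-membered ring of a ligand
#'
#' Resolves altlocs, locates the six named ring atoms and validates ring
#' geometry: consecutive (cyclic) atoms must be 1.2-1.8 Angstrom apart and
#' position 1 must be the ring's single nitrogen.
#'
#' @param ligand_atoms Atom table holding one ligand copy.
#' @param naming Atom names for ring positions 1..6
#'   (default [nicotinamide_ring_names()]).
#' @return A `ring_spec`: list with `coords` (6 x 3 matrix, rows = ring
#'   positions), `names`, and the selected `atoms`.
#' @export
assign_ring <- function(ligand_atoms, naming = nicotinamide_ring_names()) {
  if (length(naming) != 6) stop2("naming must list exactly 6 atom names")
  atoms <- resolve_altlocs(ligand_atoms)
  idx <- match(naming, atoms$elety)
  if (anyNA(idx)) stop2("ring atoms missing from ligand: ",
                        paste(naming[is.na(idx)], collapse = ", "))
  dup <- naming[vapply(naming, function(n) sum(atoms$elety == n), 1L) > 1]
  if (length(dup)) stop2("ring atom names duplicated after altloc resolution: ",
                         paste(dup, collapse = ", "),
                         " (split the ligand copies first)")
  ring <- atoms[idx, , drop = FALSE]
  coords <- as.matrix(ring[, c("x", "y", "z")])
  rownames(coords) <- as.character(1:6)
  for (i in 1:6) {
    j <- if (i == 6) 1 else i + 1
    d <- vnorm(coords[i, ] - coords[j, ])
    if (d < 1.2 || d > 1.8)
      stop2(sprintf("ring bond %s-%s is %.2f Angstrom (expected 1.2-1.8); %s",
                    naming[i], naming[j], d, "check the atom-name map"))
  }
  n_nitro <- sum(ring$element == "N")
  if (ring$element[1] != "N" || n_nitro != 1)
    stop2("ring must contain exactly one nitrogen, at position 1 (found ",
          n_nitro, ")")
  structure(list(coords = coords, names = naming, atoms = ring),
            class = "ring_spec")
}

## Least-squares plane through the four basal atoms 2,3,5,6 with the normal
## oriented by the right-handed 2 -> 3 -> 5 -> 6 circuit.
basal_plane <- function(coords) {
  base <- coords[c(2, 3, 5, 6), , drop = FALSE]
  ctr <- colMeans(base)
  centered <- sweep(base, 2, ctr)
  n <- svd(centered)$v[, 3]
  circuit <- centered
  orient <- vcross(circuit[1, ], circuit[2, ]) + vcross(circuit[2, ], circuit[3, ]) +
    vcross(circuit[3, ], circuit[4, ]) + vcross(circuit[4, ], circuit[1, ])
  if (sum(n * orient) < 0) n <- -n
  list(center = ctr, normal = n)
}

#' Ring-pucker deviation metric for a six-membered ring
#'
#' Quantifies out-of-plane displacement of the two ring "corner" atoms
#' relative to the roughly coplanar atoms 2, 3, 5 and 6. The magnitude of the
#' carbon-corner deviation is 180 degrees minus the mean absolute torsion of
#' 2-3-5-4 and 6-3-5-4; the nitrogen-corner deviation uses torsions 3-2-6-1
#' and 5-2-6-1. Signs follow a side-of-plane rule chosen so that corners
#' displaced to opposite sides of the basal plane get equal signs (chair) and
#' same-side displacement gives opposite signs (boat).
#'
#' @param ring A `ring_spec` from [assign_ring()].
#' @param planarity_tol Degrees below which a deviation counts as planar
#'   (default 2, matching the coordinate precision of ~1 Angstrom data).
#' @return A `pucker_result`: list with `delta_theta_C`, `delta_theta_N`
#'   (signed degrees), the four constituent dihedrals, apex displacements and
#'   `conformer_class`.
#' @export
compute_pucker <- function(ring, planarity_tol = 2) {
  stopifnot(inherits(ring, "ring_spec"))
  co <- ring$coords
  th2354 <- dihedral(co[2, ], co[3, ], co[5, ], co[4, ])
  th6354 <- dihedral(co[6, ], co[3, ], co[5, ], co[4, ])
  th3261 <- dihedral(co[3, ], co[2, ], co[6, ], co[1, ])
  th5261 <- dihedral(co[5, ], co[2, ], co[6, ], co[1, ])
  mag_C <- 180 - mean(c(abs(th2354), abs(th6354)))
  mag_N <- 180 - mean(c(abs(th3261), abs(th5261)))
  pl <- basal_plane(co)
  d4 <- sum((co[4, ] - pl$center) * pl$normal)
  d1 <- sum((co[1, ] - pl$center) * pl$normal)
  sgn <- function(x) if (x >= 0) 1 else -1
  delta_C <- mag_C * sgn(d4)
  delta_N <- mag_N * (-sgn(d1))
  cls <- classify_conformer(delta_C, delta_N, planarity_tol)
  structure(list(delta_theta_C = delta_C, delta_theta_N = delta_N,
                 dihedral_2354 = th2354, dihedral_6354 = th6354,
                 dihedral_3261 = th3261, dihedral_5261 = th5261,
                 apex_displacement = c(C4 = d4, N1 = d1),
                 planarity_tol = planarity_tol,
                 conformer_class = cls),
            class = "pucker_result")
}

#' @export
print.pucker_result <- function(x, ...) {
  cat(sprintf("ring pucker: delta_theta_C = %+.2f deg, delta_theta_N = %+.2f deg  [%s]\n",
              x$delta_theta_C, x$delta_theta_N, x$conformer_class))
  invisible(x)
}

#' Classify a ring conformer from its two signed deviations
#'
#' Planar if both |deviations| are within tolerance; chair if both exceed it
#' with equal signs (corners bent to opposite faces); boat if both exceed it
#' with opposite signs (same face); indeterminate if exactly one exceeds it.
#'
#' @param delta_theta_C,delta_theta_N Signed deviations in degrees. The first
#'   argument may also be a `pucker_result`.
#' @param planarity_tol Non-negative tolerance in degrees (default 2).
#' @return One of `"planar"`, `"chair"`, `"boat"`, `"indeterminate"`.
#' @export
classify_conformer <- function(delta_theta_C, delta_theta_N = NULL,
                               planarity_tol = 2) {
  if (inherits(delta_theta_C, "pucker_result")) {
    delta_theta_N <- delta_theta_C$delta_theta_N
    delta_theta_C <- delta_theta_C$delta_theta_C
  }
  if (planarity_tol < 0) stop2("planarity_tol must be >= 0")
  bigC <- abs(delta_theta_C) > planarity_tol
  bigN <- abs(delta_theta_N) > planarity_tol
  if (!bigC && !bigN) return("planar")
  if (xor(bigC, bigN)) return("indeterminate")
  if (sign(delta_theta_C) == sign(delta_theta_N)) "chair" else "boat"
}

#' Ring-pucker metrics for every copy of a ligand in a structure
#'
#' Convenience wrapper: selects the ligand by residue name (optionally chain),
#' splits copies by (chain, residue number, insertion code), and computes the
#' pucker metric for each.
#'
#' @param model A `structure_model`.
#' @param resid Ligand residue name (e.g. `"NAP"` or an adduct code).
#' @param chain Optional chain filter.
#' @param naming Ring atom-name map (see [assign_ring()]).
#' @param planarity_tol Passed to [compute_pucker()].
#' @return data.frame with one row per ligand copy: chain, resno,
#'   delta_theta_C, delta_theta_N, conformer_class.
#' @export
pucker_by_ligand <- function(model, resid, chain = NULL,
                             naming = nicotinamide_ring_names(),
                             planarity_tol = 2) {
  lig <- select_atoms(model, resid = resid, chain = chain)
  if (nrow(lig) == 0) stop2("no atoms found for ligand residue ", resid)
  keys <- unique(residue_key(lig))
  out <- lapply(keys, function(k) {
    copy <- lig[residue_key(lig) == k, , drop = FALSE]
    res <- compute_pucker(assign_ring(copy, naming), planarity_tol)
    data.frame(chain = copy$chain[1], resno = copy$resno[1],
               delta_theta_C = res$delta_theta_C,
               delta_theta_N = res$delta_theta_N,
               conformer_class = res$conformer_class,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
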