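## Polar contacts, the cross-monomer NADP(H) "seatbelt", and water bridges.
## Contacts are heavy-atom, distance-only (no angle term): deposited models
## carry no hydrogens, so proximity of N/O/S donors/acceptors is the
## operational criterion throughout.

POLAR_ELEMENTS <- c("N", "O", "S")

#' Find polar contacts between two atom selections
#'
#' Returns every N/O/S - N/O/S atom pair with one atom in each selection and
#' a distance at most `cutoff`. Symmetric duplicates (a,b)/(b,a) and
#' self-pairs are removed; each contact is annotated as cross-monomer when
#' the two atoms sit on different chains and as water-involving when either
#' residue is a water.
#'
#' @param model A `structure_model` (used only for validation; the selections
#'   carry the atoms).
#' @param selection_a,selection_b Atom tables (e.g. from [select_atoms()]).
#' @param cutoff Contact distance in Angstrom, in (2.2, 4.0); default 3.5.
#' @return data.frame of contacts: identifying columns for both atoms,
#'   `distance`, `cross_monomer`, `involves_water`. Zero rows if either
#'   selection is empty.
#' @export
find_polar_contacts <- function(model, selection_a, selection_b, cutoff = 3.5) {
  if (!is.numeric(cutoff) || cutoff <= 2.2 || cutoff >= 4.0)
    stop2("cutoff must lie in (2.2, 4.0) Angstrom")
  empty <- data.frame(eleno_a = integer(), chain_a = character(),
                      resno_a = integer(), resid_a = character(),
                      elety_a = character(), eleno_b = integer(),
                      chain_b = character(), resno_b = integer(),
                      resid_b = character(), elety_b = character(),
                      distance = numeric(), cross_monomer = logical(),
                      involves_water = logical(), stringsAsFactors = FALSE)
  pa <- selection_a[selection_a$element %in% POLAR_ELEMENTS, , drop = FALSE]
  pb <- selection_b[selection_b$element %in% POLAR_ELEMENTS, , drop = FALSE]
  if (nrow(pa) == 0 || nrow(pb) == 0) return(empty)
  d <- cross_dist(as.matrix(pa[, c("x", "y", "z")]),
                  as.matrix(pb[, c("x", "y", "z")]))
  hit <- which(d <= cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty)
  ia <- hit[, 1]; ib <- hit[, 2]
  out <- data.frame(
    eleno_a = pa$eleno[ia], chain_a = pa$chain[ia], resno_a = pa$resno[ia],
    resid_a = pa$resid[ia], elety_a = pa$elety[ia],
    eleno_b = pb$eleno[ib], chain_b = pb$chain[ib], resno_b = pb$resno[ib],
    resid_b = pb$resid[ib], elety_b = pb$elety[ib],
    distance = d[hit],
    stringsAsFactors = FALSE
  )
  out <- out[out$eleno_a != out$eleno_b, , drop = FALSE]
  key <- paste(pmin(out$eleno_a, out$eleno_b), pmax(out$eleno_a, out$eleno_b))
  out <- out[!duplicated(key), , drop = FALSE]
  out$cross_monomer <- out$chain_a != out$chain_b
  out$involves_water <- out$resid_a %in% WATER_NAMES | out$resid_b %in% WATER_NAMES
  out[order(out$distance), , drop = FALSE]
}

#' Default seatbelt contact specification
#'
#' The "seatbelt" is the cross-monomer arrangement in which arginine 314 on
#' the alpha-11 helix of one monomer reaches over the NADP(H) cofactor to
#' contact the adjacent monomer's alpha-9 helix. Required contacts: R314
#' guanidinium (NE/NH1/NH2) to D253' carboxylate (OD1/OD2) and to Q256' amide
#' (OE1/NE2). Optional (reported, not required): R314 to any water oxygen,
#' and R314 to E247' (OE1/OE2) — the latter observed only in some variants,
#' so it must not gate the verdict.
#'
#' @param cutoff Contact cutoff in Angstrom (default 3.5).
#' @return data.frame spec with one row per candidate contact.
#' @export
seatbelt_spec <- function(cutoff = 3.5) {
  data.frame(
    label    = c("R314-D253'", "R314-Q256'", "R314-water", "R314-E247'"),
    resno_a  = 314L,
    resid_a  = "ARG",
    atoms_a  = I(list(c("NE", "NH1", "NH2"), c("NE", "NH1", "NH2"),
                      c("NE", "NH1", "NH2"), c("NE", "NH1", "NH2"))),
    partner  = c("residue", "residue", "water", "residue"),
    resno_b  = c(253L, 256L, NA, 247L),
    resid_b  = c("ASP", "GLN", NA, "GLU"),
    atoms_b  = I(list(c("OD1", "OD2"), c("OE1", "NE2"), "O",
                      c("OE1", "OE2"))),
    required = c(TRUE, TRUE, FALSE, FALSE),
    cutoff   = cutoff,
    stringsAsFactors = FALSE
  )
}

#' Detect the cross-monomer NADP(H) seatbelt
#'
#' Evaluates each contact in `spec` between residue `resno_a` on
#' `chain_pair[1]` and the primed partner on `chain_pair[2]` (waters are
#' searched on any chain). A contact is found when the minimum heavy-atom
#' distance over the listed atom pairs is at most the spec cutoff. The
#' seatbelt is `present` iff every required contact is found; a named residue
#' absent from the model makes that contact absent-with-reason, never a hard
#' error.
#'
#' @param model A `structure_model`.
#' @param chain_pair Length-2 character vector `(unprimed, primed)` naming
#'   the monomer carrying R314 and the adjacent monomer.
#' @param spec Contact specification, default [seatbelt_spec()].
#' @return A `seatbelt_report`: list with `present`, `chains`, and a
#'   `contacts` data.frame (label, required, found, distance, reason).
#' @export
detect_seatbelt <- function(model, chain_pair, spec = seatbelt_spec()) {
  stopifnot(inherits(model, "structure_model"), length(chain_pair) == 2)
  rows <- lapply(seq_len(nrow(spec)), function(i) {
    s <- spec[i, ]
    a <- select_atoms(model, chain = chain_pair[1], resno = s$resno_a,
                      elety = s$atoms_a[[1]])
    if (nrow(a) == 0)
      return(data.frame(label = s$label, required = s$required, found = FALSE,
                        distance = NA_real_,
                        reason = sprintf("residue %d side-chain atoms absent from chain %s",
                                         s$resno_a, chain_pair[1]),
                        stringsAsFactors = FALSE))
    b <- if (s$partner == "water") {
      select_atoms(model, water = TRUE, elety = s$atoms_b[[1]])
    } else {
      select_atoms(model, chain = chain_pair[2], resno = s$resno_b,
                   elety = s$atoms_b[[1]])
    }
    if (nrow(b) == 0)
      return(data.frame(label = s$label, required = s$required, found = FALSE,
                        distance = NA_real_,
                        reason = if (s$partner == "water") "no water oxygens in model"
                        else sprintf("residue %d side-chain atoms absent from chain %s",
                                     s$resno_b, chain_pair[2]),
                        stringsAsFactors = FALSE))
    dmin <- min(cross_dist(as.matrix(a[, c("x", "y", "z")]),
                           as.matrix(b[, c("x", "y", "z")])))
    data.frame(label = s$label, required = s$required, found = dmin <= s$cutoff,
               distance = dmin,
               reason = if (dmin <= s$cutoff) "" else "beyond cutoff",
               stringsAsFactors = FALSE)
  })
  contacts <- do.call(rbind, rows)
  structure(list(present = all(contacts$found[contacts$required]),
                 chains = chain_pair, contacts = contacts),
            class = "seatbelt_report")
}

#' @export
print.seatbelt_report <- function(x, ...) {
  cat("seatbelt (chains ", x$chains[1], "/", x$chains[2], "'): ",
      if (x$present) "PRESENT" else "absent", "\n", sep = "")
  print(x$contacts, row.names = FALSE)
  invisible(x)
}

#' Find water molecules bridging a ligand and the protein
#'
#' A bridge is a water whose oxygen makes at least one polar contact
#' (distance at most `cutoff`) to each of the two selections; the closest
#' partner on each side is reported. Useful for spotting waters that
#' recapitulate lost side-chain interactions in mutant active sites.
#'
#' @param model A `structure_model`.
#' @param ligand_atoms,protein_atoms Disjoint atom selections.
#' @param cutoff Polar-contact cutoff in Angstrom (default 3.5).
#' @return data.frame with one row per bridging water: water identity, the
#'   closest ligand and protein partner atoms and both distances.
#' @export
find_water_bridges <- function(model, ligand_atoms, protein_atoms,
                               cutoff = 3.5) {
  if (length(intersect(ligand_atoms$eleno, protein_atoms$eleno)) > 0)
    stop2("ligand and protein selections must be disjoint")
  waters <- select_atoms(model, water = TRUE)
  waters <- waters[waters$element == "O", , drop = FALSE]
  empty <- data.frame(water_chain = character(), water_resno = integer(),
                      lig_elety = character(), lig_resno = integer(),
                      lig_dist = numeric(), prot_elety = character(),
                      prot_chain = character(), prot_resno = integer(),
                      prot_dist = numeric(), stringsAsFactors = FALSE)
  lig <- ligand_atoms[ligand_atoms$element %in% POLAR_ELEMENTS &
                        !(ligand_atoms$eleno %in% waters$eleno), , drop = FALSE]
  prot <- protein_atoms[protein_atoms$element %in% POLAR_ELEMENTS &
                          !(protein_atoms$eleno %in% waters$eleno), , drop = FALSE]
  if (nrow(waters) == 0 || nrow(lig) == 0 || nrow(prot) == 0) return(empty)
  dl <- cross_dist(as.matrix(waters[, c("x", "y", "z")]),
                   as.matrix(lig[, c("x", "y", "z")]))
  dp <- cross_dist(as.matrix(waters[, c("x", "y", "z")]),
                   as.matrix(prot[, c("x", "y", "z")]))
  rows <- lapply(seq_len(nrow(waters)), function(w) {
    il <- which.min(dl[w, ]); ip <- which.min(dp[w, ])
    if (dl[w, il] > cutoff || dp[w, ip] > cutoff) return(NULL)
    data.frame(water_chain = waters$chain[w], water_resno = waters$resno[w],
               lig_elety = lig$elety[il], lig_resno = lig$resno[il],
               lig_dist = dl[w, il],
               prot_elety = prot$elety[ip], prot_chain = prot$chain[ip],
               prot_resno = prot$resno[ip], prot_dist = dp[w, ip],
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) return(empty)
  do.call(rbind, rows)
}
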