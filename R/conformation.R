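#' Default IDH1 domain architecture
#'
#' Residue ranges (author numbering) for the homodimeric NADP+-dependent
#' IDH1 fold: each monomer has a large domain (1-103, 286-414) and small
#' domain (104-136, 186-285) that close around the active-site cleft on
#' substrate binding, pivoting at a hinge (134-141) within the clasp
#' (137-185) that holds the dimer together; the alpha-10 regulatory segment
#' (271-285) folds on closure. The alpha-9 and alpha-11 ranges bracket the
#' cross-monomer "seatbelt" residues (D253/Q256/E247 and R314 respectively);
#' their exact helix boundaries are calibration defaults and can be
#' overridden.
#'
#' @return Named list of range sets; each set is a list of `c(start, end)`
#'   inclusive integer pairs.
#' @export
idh1_domains <- function() {
  list(
    large_domain   = list(c(1L, 103L), c(286L, 414L)),
    small_domain   = list(c(104L, 136L), c(186L, 285L)),
    hinge          = list(c(134L, 141L)),
    clasp          = list(c(137L, 185L)),
    alpha10_segment = list(c(271L, 285L)),
    alpha9         = list(c(246L, 260L)),
    alpha11        = list(c(308L, 322L)),
    seatbelt       = list(c(314L, 314L), c(253L, 253L), c(256L, 256L),
                          c(247L, 247L))
  )
}

#' @keywords internal
expand_ranges <- function(ranges) {
  unlist(lapply(ranges, function(r) {
    if (r[2] < r[1]) stop2("empty residue range")
    seq.int(r[1], r[2])
  }))
}

validate_domains <- function(domains) {
  for (nm in names(domains)) {
    res <- expand_ranges(domains[[nm]])
    if (anyDuplicated(res)) stop2("overlapping ranges within domain set '", nm, "'")
  }
  invisible(domains)
}

## Resolve a probe selection (list(chain=, resno=, elety=)) to atoms and
## report how complete the selection is relative to the residues requested.
resolve_probe <- function(model, probe, label) {
  sel <- select_atoms(model, chain = probe$chain, resno = probe$resno,
                      elety = probe$elety %||% "CA")
  if (nrow(sel) == 0)
    stop2("probe selection '", label, "' resolves to no atoms")
  completeness <- length(unique(sel$resno)) / length(unique(probe$resno))
  list(centroid = colMeans(as.matrix(sel[, c("x", "y", "z")])),
       completeness = completeness)
}

#' Measure active-site and back cleft distances for each monomer
#'
#' Each cleft distance is the distance between the centroids of two probe
#' atom selections (one per cleft face). The probe configuration is recorded
#' in the output so measurements are reproducible; centroids are computed
#' over the atoms present, and calls with less than 50% probe completeness
#' (disordered loops) are flagged.
#'
#' @param model A `structure_model`.
#' @param probes Named list, one entry per monomer (chain label). Each entry
#'   is `list(active_site = list(a = <sel>, b = <sel>), back = list(a, b))`
#'   where each `<sel>` is `list(chain, resno, elety = "CA")`.
#' @return A `cleft_measurement` data.frame: one row per monomer with
#'   `monomer, active_site_cleft, back_cleft, completeness, flagged`, plus
#'   the probe configuration as attribute `"probes"`.
#' @export
measure_clefts <- function(model, probes) {
  stopifnot(inherits(model, "structure_model"), is.list(probes))
  rows <- lapply(names(probes), function(mon) {
    p <- probes[[mon]]
    meas <- vapply(c("active_site", "back"), function(cleft) {
      if (is.null(p[[cleft]])) return(c(NA_real_, NA_real_))
      a <- resolve_probe(model, p[[cleft]]$a, paste(mon, cleft, "side a"))
      b <- resolve_probe(model, p[[cleft]]$b, paste(mon, cleft, "side b"))
      c(vnorm(a$centroid - b$centroid), min(a$completeness, b$completeness))
    }, numeric(2))
    data.frame(monomer = mon,
               active_site_cleft = meas[1, "active_site"],
               back_cleft = meas[1, "back"],
               completeness = min(meas[2, ], na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$flagged <- out$completeness < 0.5
  attr(out, "probes") <- probes
  class(out) <- c("cleft_measurement", class(out))
  out
}

#' Classify open / semi-closed / closed conformation from cleft geometry
#'
#' A pure, monotone mapping of the active-site cleft distance: at or below
#' the closed cutoff -> closed; above the open cutoff -> open; between ->
#' semi-closed. A measurement exactly at a cutoff is assigned to the
#' more-closed class. The back cleft is carried along as a corroborating
#' metric but does not enter the call.
#'
#' @param measurement A `cleft_measurement` row set from [measure_clefts()],
#'   or a data.frame with an `active_site_cleft` column.
#' @param thresholds Named numeric `c(closed = ..., open = ...)` in Angstrom;
#'   must satisfy closed < open. Defaults `c(closed = 11, open = 14)` are
#'   calibration values, not claims about any deposited structure.
#' @return A `conformation_call` data.frame: the measurements plus a `state`
#'   column in `{"closed", "semi-closed", "open"}` and the thresholds used as
#'   attribute `"thresholds"`.
#' @export
classify_conformation <- function(measurement,
                                  thresholds = c(closed = 11, open = 14)) {
  if (!all(c("closed", "open") %in% names(thresholds)))
    stop2("thresholds must be named c(closed=, open=)")
  if (!(thresholds[["closed"]] < thresholds[["open"]]))
    stop2("inverted thresholds: require closed < open")
  d <- measurement$active_site_cleft
  state <- ifelse(d <= thresholds[["closed"]], "closed",
                  ifelse(d <= thresholds[["open"]], "semi-closed", "open"))
  out <- measurement
  out$state <- state
  attr(out, "thresholds") <- thresholds
  class(out) <- unique(c("conformation_call", class(out)))
  out
}
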