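## Synthetic-data generators. Every generator returns its ground truth (as an
## attribute or list element) and is fully seed-controlled, so each analysis
## stage has a round-trip oracle without any external downloads.

#' Generate a six-membered ring with prescribed pucker deviations
#'
#' Places ring atoms 2, 3, 5, 6 exactly on a planar hexagonal footprint and
#' solves numerically for the out-of-plane displacement of the two corner
#' atoms (1 and 4) that reproduces the requested deviations under the
#' pucker-metric definition, preserving 1.4 Angstrom ring bonds by pulling
#' the displaced corners radially inward. Positive/negative targets place the
#' corners so that [compute_pucker()] recovers the prescribed signs.
#'
#' @param delta_theta_C,delta_theta_N Target signed deviations in degrees
#'   (|target| <= 60; large targets beyond the geometric limit error out).
#' @param bond Ring bond length in Angstrom (default 1.4).
#' @param naming Atom names for positions 1..6
#'   (default [nicotinamide_ring_names()]).
#' @param resid Residue name of the generated ligand (default "NAP").
#' @param chain Chain label (default "L").
#' @return A `structure_model` holding the 6-atom ligand; the targets are
#'   stored in attribute `"truth"`.
#' @export
generate_ring <- function(delta_theta_C, delta_theta_N, bond = 1.4,
                          naming = nicotinamide_ring_names(),
                          resid = "NAP", chain = "L") {
  if (abs(delta_theta_C) > 60 || abs(delta_theta_N) > 60)
    stop2("|delta theta| targets must be <= 60 degrees")
  R <- bond   # regular hexagon: circumradius equals side length
  ang <- (0:5) * pi / 3
  hexagon <- cbind(R * cos(ang), R * sin(ang), 0)

  ## corner position at out-of-plane height h, pulled inward to keep the
  ## bonds to both in-plane neighbours at `bond`:
  ## a^2 - a R + h^2 = 0  =>  a = (R + sqrt(R^2 - 4 h^2)) / 2
  corner_at <- function(pos, h) {
    if (4 * h^2 > R^2) stop2("target pucker beyond geometric limit")
    a <- (R + sqrt(R^2 - 4 * h^2)) / 2
    c(a * cos(ang[pos]), a * sin(ang[pos]), h)
  }
  magnitude_at <- function(pos, h) {
    co <- hexagon
    co[pos, ] <- corner_at(pos, h)
    if (pos == 4)
      180 - mean(c(abs(dihedral(co[2, ], co[3, ], co[5, ], co[4, ])),
                   abs(dihedral(co[6, ], co[3, ], co[5, ], co[4, ]))))
    else
      180 - mean(c(abs(dihedral(co[3, ], co[2, ], co[6, ], co[1, ])),
                   abs(dihedral(co[5, ], co[2, ], co[6, ], co[1, ]))))
  }
  solve_height <- function(pos, target_mag) {
    if (target_mag < 1e-12) return(0)
    hmax <- R / 2 * 0.999
    if (magnitude_at(pos, hmax) < target_mag)
      stop2("target pucker beyond geometric limit")
    stats::uniroot(function(h) magnitude_at(pos, h) - target_mag,
                   lower = 0, upper = hmax, tol = 1e-12)$root
  }
  h4 <- solve_height(4, abs(delta_theta_C))
  h1 <- solve_height(1, abs(delta_theta_N))
  co <- hexagon
  ## basal-plane normal is +z for this footprint; the sign rule is
  ## sign(dC) = sign(z4) and sign(dN) = -sign(z1)
  co[4, ] <- corner_at(4, h4 * ifelse(delta_theta_C >= 0, 1, -1))
  co[1, ] <- corner_at(1, h1 * ifelse(delta_theta_N >= 0, -1, 1))
  elements <- c("N", rep("C", 5))
  atoms <- data.frame(
    eleno = 1:6, chain = chain, resno = 500L, insert = "", resid = resid,
    elety = naming, element = elements,
    x = co[, 1], y = co[, 2], z = co[, 3], o = 1, alt = "",
    is_water = FALSE, is_hetero = TRUE, stringsAsFactors = FALSE
  )
  model <- new_structure_model(atoms, source_id = "synthetic-ring")
  attr(model, "truth") <- list(delta_theta_C = delta_theta_C,
                               delta_theta_N = delta_theta_N, bond = bond)
  model
}

toy_atom <- function(eleno, chain, resno, resid, elety, xyz,
                     hetero = FALSE, water = FALSE) {
  data.frame(eleno = eleno, chain = chain, resno = as.integer(resno),
             insert = "", resid = resid, elety = elety,
             element = element_from_name(elety),
             x = xyz[1], y = xyz[2], z = xyz[3], o = 1, alt = "",
             is_water = water, is_hetero = hetero | water,
             stringsAsFactors = FALSE)
}

#' Default cleft probe configuration for the toy dimer
#'
#' Matches the probe residues placed by [generate_toy_dimer()]: three CA
#' atoms per cleft face (residues 120-122 vs 290-292 for the active-site
#' cleft, 150-152 vs 350-352 for the back cleft), per chain.
#'
#' @param chains Chains to build probes for (default A and B).
#' @return Probe list in the shape [measure_clefts()] expects.
#' @export
toy_dimer_probes <- function(chains = c("A", "B")) {
  out <- lapply(chains, function(ch) list(
    active_site = list(a = list(chain = ch, resno = 120:122, elety = "CA"),
                       b = list(chain = ch, resno = 290:292, elety = "CA")),
    back = list(a = list(chain = ch, resno = 150:152, elety = "CA"),
                b = list(chain = ch, resno = 350:352, elety = "CA"))
  ))
  names(out) <- chains
  out
}

#' Generate a toy two-chain dimer with known seatbelt and cleft geometry
#'
#' Builds a minimal structure exercising the production analysis paths:
#' chain A carries an arginine 314 whose guanidinium atoms sit 2.5-2.9
#' Angstrom from the aspartate 253 / glutamine 256 (and glutamate 247) polar
#' atoms of chain B when `seatbelt = TRUE` (displaced 6 Angstrom away when
#' `FALSE`), a seatbelt water, an NADP ligand fragment with a bridging water
#' to a protein serine, and per-chain CA probe clusters whose centroid
#' separations encode the requested cleft state (active-site cleft 10 /
#' 12.5 / 15 Angstrom for closed / semi / open; back cleft 11 / 9.5 / 8,
#' moving oppositely).
#'
#' @param seatbelt Place the cross-monomer seatbelt contacts (default TRUE).
#' @param cleft_state `"closed"`, `"semi"` or `"open"`.
#' @return A `structure_model` with ground truth in attribute `"truth"`.
#' @export
generate_toy_dimer <- function(seatbelt = TRUE,
                               cleft_state = c("closed", "semi", "open")) {
  cleft_state <- match.arg(cleft_state)
  clefts <- list(closed = c(active = 10, back = 11),
                 semi   = c(active = 12.5, back = 9.5),
                 open   = c(active = 15, back = 8))[[cleft_state]]
  shift <- if (seatbelt) c(0, 0, 0) else c(0, 0, 6)  # pull R314 away
  rows <- list(
    ## chain A: seatbelt arginine
    toy_atom(0, "A", 314, "ARG", "CA",  c(-2.0, -1.0, -1.0) + shift),
    toy_atom(0, "A", 314, "ARG", "NE",  c(-1.2,  0.0,  0.0) + shift),
    toy_atom(0, "A", 314, "ARG", "NH1", c( 0.0,  0.0,  0.0) + shift),
    toy_atom(0, "A", 314, "ARG", "NH2", c( 0.0, -1.2,  0.0) + shift),
    ## chain B: primed partners
    toy_atom(0, "B", 253, "ASP", "CA",  c(4.5,  0.5, -1.5)),
    toy_atom(0, "B", 253, "ASP", "OD1", c(2.9,  0.0,  0.0)),
    toy_atom(0, "B", 253, "ASP", "OD2", c(3.6, -1.1,  0.0)),
    toy_atom(0, "B", 256, "GLN", "CA",  c(0.5,  4.5, -1.5)),
    toy_atom(0, "B", 256, "GLN", "OE1", c(0.0,  2.9,  0.0)),
    toy_atom(0, "B", 256, "GLN", "NE2", c(1.1,  3.6,  0.0)),
    toy_atom(0, "B", 247, "GLU", "CA",  c(0.5, -5.0, -2.0)),
    toy_atom(0, "B", 247, "GLU", "OE1", c(0.0, -3.5, -1.0)),
    toy_atom(0, "B", 247, "GLU", "OE2", c(1.0, -4.4, -1.0)),
    ## seatbelt water (near R314 guanidinium when present)
    toy_atom(0, "A", 601, "HOH", "O",   c(0.0, 0.0, 2.8), water = TRUE),
    ## NADP ligand fragment + bridging water to a protein serine
    toy_atom(0, "A", 500, "NAP", "O1",  c(12.0, 12.0, 0.0), hetero = TRUE),
    toy_atom(0, "A", 500, "NAP", "N1",  c(13.4, 12.0, 0.0), hetero = TRUE),
    toy_atom(0, "A", 500, "NAP", "C1",  c(12.7, 12.0, 1.2), hetero = TRUE),
    toy_atom(0, "A", 602, "HOH", "O",   c(12.0, 12.0, 2.8), water = TRUE),
    toy_atom(0, "A", 310, "SER", "OG",  c(12.0, 12.0, 5.7)),
    toy_atom(0, "A", 310, "SER", "CA",  c(12.0, 13.4, 6.3))
  )
  ## cleft probe clusters: per chain, CA triplets whose centroids sit exactly
  ## `clefts` apart, well away (y offsets) from the contact zone
  add_probes <- function(rows, chain, ybase) {
    mk <- function(resno_a, resno_b, origin, sep) {
      lapply(0:2, function(i) {
        a <- toy_atom(0, chain, resno_a + i, "GLY", "CA",
                      origin + c(i - 1, 0, 0))
        b <- toy_atom(0, chain, resno_b + i, "GLY", "CA",
                      origin + c(i - 1, sep, 0))
        rbind(a, b)
      })
    }
    c(rows,
      mk(120, 290, c(0, ybase, 0), clefts[["active"]]),
      mk(150, 350, c(0, ybase, 20), clefts[["back"]]))
  }
  rows <- add_probes(rows, "A", 30)
  rows <- add_probes(rows, "B", -40)
  atoms <- do.call(rbind, rows)
  atoms$eleno <- seq_len(nrow(atoms))
  model <- new_structure_model(atoms, source_id = "synthetic-toy-dimer")
  attr(model, "truth") <- list(seatbelt = seatbelt, cleft_state = cleft_state,
                               active_site_cleft = clefts[["active"]],
                               back_cleft = clefts[["back"]],
                               probes = toy_dimer_probes())
  model
}

#' Simulate a peptide-level HDX-MS experiment
#'
#' True peptide uptake is the sum over exchangeable amides of
#' `1 - exp(-k_int * t / P_i)` (intrinsic exchange slowed by the per-residue
#' protection factor P_i); measured uptake applies the back-exchange loss
#' `(1 - be)` and Gaussian replicate noise. Output is exactly the table
#' dialect [load_peptide_table()] reads, with ground truth attached.
#'
#' @param peptides data.frame with columns `start`, `end`, `sequence`.
#' @param protection Per-residue protection factors (>= 1): either a single
#'   value or a vector indexed by residue number up to `max(end)`.
#' @param k_int Intrinsic amide exchange rate, 1/min (default 10; a hook for
#'   per-residue rates: vector indexed like `protection`).
#' @param times Exposure schedule in minutes (default 0, 0.5, 1, 2, 5).
#' @param replicates Technical replicates per timepoint (default 3).
#' @param sigma Gaussian noise SD in Da (default 0.05).
#' @param be Back-exchange fraction (default 0.25).
#' @param state State label for the output table.
#' @param seed Integer seed controlling the noise.
#' @return data.frame in the peptide-table dialect with an `uptake` column
#'   and attribute `"truth"` (per-peptide true uptake by time, parameters).
#' @export
simulate_hdx <- function(peptides, protection = 100, k_int = 10,
                         times = c(0, 0.5, 1, 2, 5), replicates = 3,
                         sigma = 0.05, be = 0.25, state = "stateA",
                         seed = 1) {
  stopifnot(all(c("start", "end", "sequence") %in% names(peptides)))
  if (any(protection < 1)) stop2("protection factors must be >= 1")
  if (any(k_int <= 0)) stop2("intrinsic rates must be positive")
  if (be < 0 || be >= 1) stop2("be must be in [0, 1)")
  nres <- max(peptides$end)
  pf <- if (length(protection) == 1) rep(protection, nres) else protection
  ki <- if (length(k_int) == 1) rep(k_int, nres) else k_int
  if (length(pf) < nres || length(ki) < nres)
    stop2("protection/k_int vectors must cover residues 1..", nres)
  set.seed(seed)
  rows <- list(); truth <- list()
  for (p in seq_len(nrow(peptides))) {
    st <- peptides$start[p]; en <- peptides$end[p]
    seqp <- peptides$sequence[p]
    exch <- st + exchangeable_positions(seqp) - 1   # absolute residue numbers
    true_uptake <- vapply(times, function(t)
      sum(1 - exp(-ki[exch] * t / pf[exch])), 1)
    truth[[p]] <- list(start = st, end = en, sequence = seqp, times = times,
                       true_uptake = true_uptake, exchangeable = exch)
    for (i in seq_along(times)) {
      measured <- true_uptake[i] * (1 - be) +
        stats::rnorm(replicates, 0, sigma)
      rows[[length(rows) + 1]] <- data.frame(
        state = state, start = st, end = en, sequence = seqp,
        exposure_min = times[i], replicate = seq_len(replicates),
        value = measured, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$uptake <- out$value
  attr(out, "truth") <- list(peptides = truth, protection = pf, k_int = ki,
                             sigma = sigma, be = be, seed = seed)
  out
}

#' Write a simulated peptide table in the loader's text dialect
#'
#' @param table Output of [simulate_hdx()].
#' @param path Destination file (comma-separated).
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(table, path) {
  utils::write.csv(
    table[, c("state", "start", "end", "sequence", "exposure_min",
              "replicate", "value")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Simulate a stopped-flow kinetic trace
#'
#' Evaluates the exact model (single exponential or two-step sequential) on
#' the sampling grid and adds seeded Gaussian noise. True parameters travel
#' in the trace metadata.
#'
#' @param model `"single_exp"` or `"two_step"`.
#' @param A0 Amplitude (negative for decaying signals under `"two_step"`).
#' @param k Rate for `"single_exp"` (1/s).
#' @param k1,k2 Step rates for `"two_step"` (1/s).
#' @param baseline Baseline offset.
#' @param sigma Noise SD in signal units.
#' @param times Sampling grid in seconds.
#' @param direction `"decay"` (`A0*exp(-kt)`) or `"rise"` (`A0*(1-exp(-kt))`)
#'   for the single-exponential model.
#' @param seed Integer seed.
#' @return A `kinetic_trace` with truth in its metadata.
#' @export
simulate_trace <- function(model = c("single_exp", "two_step"), A0 = 1,
                           k = 1, k1 = 5, k2 = 0.5, baseline = 0,
                           sigma = 0, times = seq(0, 10, length.out = 200),
                           direction = c("decay", "rise"), seed = 1) {
  model <- match.arg(model); direction <- match.arg(direction)
  y <- if (model == "single_exp") {
    if (k <= 0) stop2("rates must be positive")
    if (direction == "decay") A0 * exp(-k * times) + baseline
    else A0 * (1 - exp(-k * times)) + baseline
  } else {
    if (k1 <= 0 || k2 <= 0) stop2("rates must be positive")
    two_step_signal(times, A0, k1, k2, baseline)
  }
  set.seed(seed)
  if (sigma > 0) y <- y + stats::rnorm(length(times), 0, sigma)
  kinetic_trace(times, y, metadata = list(
    model = model, A0 = A0, k = k, k1 = k1, k2 = k2, baseline = baseline,
    sigma = sigma, direction = direction, seed = seed))
}

#' Simulate steady-state Michaelis-Menten rate data
#'
#' `v = kcat * E * [S] / (Km * (1 + [I]/Ki) + [S])` plus relative Gaussian
#' noise; the competitive-inhibition extension is used for Lineweaver-Burk
#' tests. `se` is reported as the noise SD per point (floored at a small
#' positive value so weighted fits are defined in the noiseless case).
#'
#' @param kcat Turnover number (1/s).
#' @param Km Michaelis constant (concentration units of `s_grid`).
#' @param enzyme_conc Total enzyme concentration.
#' @param s_grid Substrate concentrations (default 8 points log-spaced on
#'   `[Km/10, 10*Km]`).
#' @param sigma_rel Relative noise SD (default 0).
#' @param inhibitor_conc,Ki Competitive inhibitor concentration and constant
#'   (`inhibitor_conc = 0` disables inhibition).
#' @param seed Integer seed.
#' @return data.frame `conc, rate, se, inhibitor` with truth attached as
#'   attribute `"truth"`.
#' @export
simulate_mm <- function(kcat, Km, enzyme_conc,
                        s_grid = exp(seq(log(Km / 10), log(10 * Km),
                                         length.out = 8)),
                        sigma_rel = 0, inhibitor_conc = 0, Ki = Inf,
                        seed = 1) {
  if (kcat <= 0 || Km <= 0 || enzyme_conc <= 0)
    stop2("kcat, Km and enzyme_conc must be positive")
  km_app <- Km * (1 + inhibitor_conc / Ki)
  v <- kcat * enzyme_conc * s_grid / (km_app + s_grid)
  set.seed(seed)
  noise <- if (sigma_rel > 0) stats::rnorm(length(v), 0, sigma_rel * v) else 0
  out <- data.frame(conc = s_grid, rate = v + noise,
                    se = pmax(sigma_rel * v, 1e-9 * max(v)),
                    inhibitor = inhibitor_conc)
  attr(out, "truth") <- list(kcat = kcat, Km = Km, enzyme_conc = enzyme_conc,
                             efficiency = kcat / Km, Ki = Ki,
                             inhibitor_conc = inhibitor_conc,
                             sigma_rel = sigma_rel, seed = seed)
  out
}
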