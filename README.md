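# remodelkit

Structural and kinetic analysis of active-site remodeling in IDH1 variants.

Isocitrate dehydrogenase 1 (IDH1) is a homodimeric NADP(H)-dependent enzyme.
Tumor-associated mutations at arginine 132 (R132H, R132Q) create a neomorphic
activity — reduction of alpha-ketoglutarate to the oncometabolite
D-2-hydroxyglutarate — with catalytic efficiencies that differ by orders of
magnitude between mutants. Those differences track with three measurable
properties of the enzyme, and this package provides quantitative tools for
each:

- **Nicotinamide ring pucker** (`compute_pucker()`): the signed
  delta-theta deviation metric with chair / boat / planar classification,
  distinguishing the reactive planar NADP(H) cofactor from covalent
  NADP-adducts. `Δθ_C = 180° − mean(|θ(2-3-5-4)|, |θ(6-3-5-4)|)` and
  `Δθ_N = 180° − mean(|θ(3-2-6-1)|, |θ(5-2-6-1)|)`, signed by a
  side-of-basal-plane rule: equal signs → chair, opposite → boat.
- **Conformational state and contacts** (`measure_clefts()`,
  `classify_conformation()`, `find_polar_contacts()`, `detect_seatbelt()`,
  `find_water_bridges()`): cleft-width based open / semi-closed / closed
  calls, polar-contact enumeration, and detection of the cross-monomer
  "seatbelt" (R314 to D253′/Q256′ of the partner chain, plus optional water
  and E247′ contacts) that pins the cofactor in catalytically competent
  dimers.
- **HDX-MS uptake** (`load_peptide_table()`, `uptake_curves()`,
  `compare_states()`, `equilibration_time()`, `map_uptake_to_structure()`):
  peptide-level deuterium uptake `Σ_i (1 − e^{−k_int t / P_i})` with global
  back-exchange correction `corrected = measured / (1 − BE)`, per-timepoint +
  overall significance testing, and exchange-equilibration times (t95).
- **Kinetics** (`fit_single_exponential()`, `assess_lag()`,
  `fit_binding_line()`, `fit_michaelis_menten()`, `lineweaver_burk()`,
  `efficiency_fold_change()`): single-exponential traces `Y = A0 e^{−kt} + c`,
  AICc + CUSUM lag-phase assessment against a two-step sequential model,
  cofactor-binding lines `k_obs = k1[L] + k_-1`, Michaelis–Menten fits with
  kcat/Km fold changes and propagated uncertainties.
- **Synthetic data** (`generate_ring()`, `generate_toy_dimer()`,
  `simulate_hdx()`, `simulate_trace()`, `simulate_mm()`): seed-controlled
  generators that emit their own ground truth, so every analysis stage has a
  round-trip oracle without downloads.

Structure I/O (`read_structure()`, `write_structure()`, `select_atoms()`,
`residues_within()`, `superpose()`) wraps PDB/mmCIF parsing via
[bio3d](https://cran.r-project.org/package=bio3d); nonlinear fitting uses
[minpack.lm](https://cran.r-project.org/package=minpack.lm).

## Worked example

```r
library(remodelkit)

## 1. Ring pucker: generate a boat-puckered nicotinamide ring and recover it
m <- generate_ring(25, -25)
compute_pucker(assign_ring(select_atoms(m, resid = "NAP")))
#> ring pucker: delta_theta_C = +25.00 deg, delta_theta_N = -25.00 deg  [boat]

## 2. Seatbelt and conformation on a synthetic dimer
dimer <- generate_toy_dimer(seatbelt = TRUE, cleft_state = "semi")
detect_seatbelt(dimer, c("A", "B"))
#> seatbelt (chains A/B'): PRESENT
#>       label required found distance reason
#>  R314-D253'     TRUE  TRUE 2.900000
#>  R314-Q256'     TRUE  TRUE 2.900000
#>  R314-water    FALSE  TRUE 2.800000
#>  R314-E247'    FALSE  TRUE 2.507987

classify_conformation(measure_clefts(dimer, toy_dimer_probes()))
#>              monomer active_site_cleft back_cleft completeness flagged       state
#> active_site        A              12.5        9.5            1   FALSE semi-closed
#> active_site1       B              12.5        9.5            1   FALSE semi-closed

## 3. HDX-MS: compare a protected (WT-like) and deprotected (mutant-like) state
peps <- data.frame(start = 210L, end = 216L, sequence = "LGWTKPI")
wt  <- simulate_hdx(peps, protection = 500, state = "WT",    seed = 1)
mut <- simulate_hdx(peps, protection = 5,   state = "R132Q", seed = 2)
cmp <- compare_states(rbind(wt, mut))
cmp$overall_p; cmp$significant
#> overall p = 1.5e-14, significant = TRUE
cmp$per_time
#>   time diff_corrected            p
#> 1  0.5      -2.440181 1.360831e-06
#> 2  1.0      -3.393925 1.578866e-07
#> 3  2.0      -3.762437 8.753569e-08
#> 4  5.0      -3.664965 1.800364e-06

## 4. Kinetics: catalytic-efficiency fold change between two variants
fa <- fit_michaelis_menten(simulate_mm(10, 100, 0.2, sigma_rel = 0.05, seed = 3), 0.2)
fb <- fit_michaelis_menten(simulate_mm(10, 940, 0.2, sigma_rel = 0.05, seed = 4), 0.2)
efficiency_fold_change(fa, fb)
#> $fold_change
#> [1] 8.775328
#>
#> $se
#> [1] 0.3451426
```

(The true induced fold change in step 4 is 9.4; the estimate above is from a
single noisy simulated dataset and carries a propagated standard error.)

A command-line interface covering the same operations ships in
`inst/scripts/remodelkit` (e.g.
`remodelkit pucker --pdb structure.pdb`,
`remodelkit simulate mm --out dir --seed 3`).

## Methods

See the vignette source at `vignettes/methods.Rmd` for the models,
conventions (dihedral sign convention, pucker sign rule, conjunction rule
for HDX significance, CUSUM lag criterion) and the rationale behind every
default threshold.
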