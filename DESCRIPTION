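Package: remodelkit
Title: Structural and Kinetic Analysis of Active-Site Remodeling in IDH1 Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative tools for comparing isocitrate dehydrogenase 1 (IDH1)
    variants from structural and biophysical data: a nicotinamide ring-pucker
    deviation metric (delta-theta) with chair/boat classification, cleft-based
    open/semi-closed/closed conformational calls for enzyme dimers, detection of
    polar contacts, the cross-monomer NADP(H) "seatbelt" and water-mediated
    bridges, hydrogen/deuterium-exchange mass-spectrometry (HDX-MS) uptake
    analysis with global back-exchange correction and state comparison, and
    pre-steady-state/steady-state kinetic fitting (single-exponential traces,
    lag-phase assessment, cofactor-binding lines, Michaelis-Menten and
    Lineweaver-Burk). A synthetic-data module generates every input with known
    ground truth so each stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
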