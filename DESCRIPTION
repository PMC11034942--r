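Package: qsipgrowth
Title: Taxon-Specific Bacterial Growth from 18O Quantitative Stable
    Isotope Probing with Factorial Climate-Interaction Typing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates taxon-specific soil bacterial growth rates from
    density-fractionated 16S rRNA amplicon data using 18O-water
    quantitative stable isotope probing (qSIP): weighted-average buoyant
    density, excess atom fraction 18O, per-taxon growth rates with
    bootstrap confidence intervals and incorporator calling. Computes
    single-factor and combined climate effect sizes (log response
    ratios), the small-sample-corrected standardized interaction effect
    (Hedges' d) for 2x2 factorial warming x precipitation designs,
    classifies taxa into five interaction types (additive, synergistic,
    weak/strong antagonistic, neutralizing) with a 5-point antagonism
    intensity scale, and tests phylogenetic clustering of response
    groups via the nearest taxon index (NTI). Includes a forward
    simulator of the density-gradient experiment with known ground
    truth for validation by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    igraph,
    jsonlite,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
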