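Package: nmr2
Title: NMR Molecular Replacement for Protein-Ligand Complexes from Unassigned Methyl NOEs
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Determines ligand binding poses against a known receptor structure
    from unassigned, ambiguous NOESY data, following the NMR molecular
    replacement (NMR2) strategy. Fits NOESY build-up curves with a two-spin
    cross-relaxation model, converts cross-relaxation rates to distances via
    isotropic spectral densities, calibrates ambiguous upper-limit restraints
    with methyl-dependent tolerances, derives conservative anti-NOE lower
    limits from confidently absent cross peaks, enumerates methyl resonance
    assignment hypotheses restricted by residue-type classes, anchors and
    prochiral pairing, and ranks them by the target function of a simulated
    annealing ligand pose search. A full relaxation-matrix NOESY simulator
    over a synthetic binding pocket provides ground-truth data for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
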