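Package: icmsans
Title: Inverse Contrast-Matching Small-Angle Neutron Scattering Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for small-angle neutron scattering (SANS) studies of
    proteins in deuterated molecular-crowding environments by inverse
    contrast matching. Covers scattering-length-density and contrast-match
    arithmetic for solvents and deuterated biomolecular compositions,
    solute-intensity data reduction from solution/solvent/empty-cell
    measurements, curve-level statistics (integrated small-q intensity,
    contrast-match-point regression, Porod/mass-fractal slopes,
    interference-peak detection with harmonic assignment and Bragg
    spacings), an orientationally averaged Debye scattering simulator for
    atomic and bead models in H2O/D2O solvents with exchangeable-hydrogen
    substitution, excluded volume and a hydration shell, fibril
    super-assembly builders (axial elongation, lateral pairs, idealized
    cross-beta units), ab initio bead modeling by simulated annealing with
    normalized-spatial-discrepancy model comparison, and synthetic-data
    generators (mass-fractal debris curves, off-lattice diffusion-limited
    aggregates, contrast series, fibrillization time courses) for
    closed-loop validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    minpack.lm,
    bio3d,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
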