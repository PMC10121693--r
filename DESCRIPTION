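Package: decoychemo
Title: Decoy-Receptor Chemotaxis in a Boyden Chamber
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Deterministic simulation of glioma-cell migration through a
    Boyden-chamber filter driven by CD95/CD95L receptor-ligand kinetics in
    the presence of the decoy receptor DcR3.  Implements the well-mixed
    mass-action kinetics, a four-field Keller-Segel-type
    reaction-advection-diffusion system on the chamber geometry (cell
    density, ligand, bound normal receptors, bound decoy receptors), the
    reduced no-decoy system, migration observables (filter cell count and
    wavefront penetration depth), ligand-concentration sweeps with
    golden-section refinement of the over-stimulation threshold, and local
    forward sensitivity analysis of the migrated-cell count with a
    finite-difference cross-check.  Time stepping uses the explicit Euler
    scheme or a Crank-Nicolson IMEX alternative, both implemented in C++.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
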