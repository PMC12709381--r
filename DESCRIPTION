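Package: dlvoreg
Title: Charge-Regulated DLVO Analysis of Surface Force Balance Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing force-distance curves between charged surfaces
    in aqueous electrolytes, as measured by the surface force balance (SFB).
    Implements the DLVO interaction free energy with the constant charge
    regulation approximation (van der Waals attraction plus electric double
    layer repulsion with a regulation parameter p interpolating between
    constant-potential and constant-charge boundary conditions), electrolyte
    utilities (Debye screening length, Grahame equation, thermal voltage,
    van't Hoff osmotic pressure), a numerical Poisson-Boltzmann two-plate
    solver used as an independent oracle for the weak-overlap model, a
    quasi-static SFB simulator producing synthetic approach/retraction curves
    with spring-instability jumps, structural layering and adhesion, and a
    fitting/feature-extraction pipeline that recovers effective surface
    potential, screening length and regulation parameter from measured or
    simulated curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    minpack.lm,
    jsonlite,
    yaml,
    tibble,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
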