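Package: pslifetime
Title: Ortho-Positronium Lifetime Imaging Feasibility for Total-Body PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Feasibility toolkit for mean ortho-positronium lifetime imaging
    with two back-to-back 511 keV annihilation photons plus a 1160 keV prompt
    gamma (2g + prompt triple coincidences) on total-body PET scanners.
    Provides an analytic sensitivity model for cylindrical LYSO and plastic
    scintillator scanners as a function of the axial field of view, a
    vectorized Monte Carlo of an idealized plastic-scintillator total-body
    scanner (ray tracing through cylindrical layers, Klein-Nishina Compton
    deposits, Gaussian position and time smearing, triple-coincidence
    selection), time-of-flight event reconstruction, direct and TOF
    filtered-back-projection images with point-spread-function extraction,
    and per-voxel positronium lifetime estimation with resolution studies
    as a function of the coincidence resolving time.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    minpack.lm,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
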