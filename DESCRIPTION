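Package: sphvalve
Title: Coupled SPH-Finite-Element Simulation of Heart Valve
    Fluid-Structure Interaction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale simulator for intraventricular hemodynamics and
    heart-valve dynamics.  Blood is modelled with a weakly-compressible
    smoothed particle hydrodynamics (SPH) solver, valve tissue with an
    explicit-dynamics finite-element solver (anisotropic
    Holzapfel-Gasser-Ogden membranes for leaflets, Ogden trusses for
    chordae tendineae), and the two are coupled through node-to-surface
    penalty contact.  Includes prescribed-motion cardiac walls driven by
    periodic keyframe splines, pressure-piston boundaries, a synthetic
    scene generator (hydrostatic tank, plane Poiseuille channel, elastic
    gate, tri-leaflet tube valve, idealized truncated-ellipsoid left
    ventricle), and clinical post-processing metrics (stroke volume,
    ejection fraction, effective orifice areas, regurgitant volume and
    fraction, transvalvular pressure drops, hydrodynamic axial forces,
    rapid valve opening/closing times, E/A ratio, opening angles).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
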