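Package: cytomech
Title: Dissipative Particle Dynamics Simulation of Cell Membrane and
    Cytoskeleton Mechanics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Coarse-grained mechanical model of a suspended cell built from
    dissipative particle dynamics (DPD): a closed triangulated membrane of
    worm-like-chain bonds with bending, area and volume constraints, and a
    cross-linked filament/ACP cytoskeletal network with stochastic Bell-model
    binding kinetics.  Implements four virtual mechanical assays on that
    model: particle-tracking microrheology (mean-square displacement and the
    generalized Stokes-Einstein conversion to storage/loss moduli), two-plate
    oscillatory bulk rheology, conical indentation with Sneddon fitting of
    the force-indentation curve, and micropipette microinjection with
    membrane-rupture detection and finite-strain field analysis of the
    resulting deformation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
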