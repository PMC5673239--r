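Package: gatemetrics
Title: Structural and Dynamic Observables for Pentameric Ligand-Gated Ion
    Channel Gating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the quaternary conformational changes that open and
    close pentameric ligand-gated ion channels (pLGICs). Implements the
    global twisting angle of the extracellular domain relative to the
    transmembrane domain, the polar (blooming) and azimuthal components of
    extracellular subunit tilt, the C-alpha cross-section and sphere-fit
    radius profile of the ion pore with constriction detection, water and
    ion pore occupancy, transmembrane permeation (flux) counting with
    periodic-boundary safeguards, axial water-density profiles and
    dehydrated-stretch measurement, interfacial loop geometry (M2-M3
    proline projection, beta1-beta2 vertical separation, binding-site
    distances, side-chain rotamers), and trajectory statistics
    (superposition, RMSD series, block averaging, autocorrelation with
    exponential fits). A synthetic C5-symmetric pentamer and solvent
    simulator provide ground-truth trajectories for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    graphics,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
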