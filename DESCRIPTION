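Package: dbsvcm
Title: Volume Conductor Modelling for Deep Brain Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Automated volume-conductor simulation of deep brain stimulation
    (DBS). Solves the dispersive electro-quasistatic field problem over the
    frequency spectrum of the stimulus on an adaptively refined tetrahedral
    mesh, with heterogeneous and anisotropic tissue properties mapped from
    voxel data (4-term Cole-Cole dispersion, DTI-derived conductivity
    tensors), a constant-phase-element model of the electrode-tissue
    interface, current- and voltage-controlled stimulation modes, and
    threshold-based estimation of axonal activation. Ships synthetic tissue
    phantoms and parametric toy electrodes so the full pipeline runs without
    external imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    tools,
    parallel
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    optparse
Config/testthat/edition: 3
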