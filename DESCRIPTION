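Package: peristMHD
Title: Peristaltic Transport of a Jeffrey Fluid in an Inclined Channel
    Under an Inclined Magnetic Field with Heat Transfer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form lubrication-limit (long-wavelength, low-Reynolds)
    solutions for peristaltic transport of a Jeffrey-type viscoelastic fluid
    through a two-dimensional inclined symmetric channel, subject to an
    inclined applied magnetic field, gravity, buoyancy and a volumetric heat
    source or sink.  Provides the coupled temperature and axial-velocity
    fields, shear stress, pressure-gradient/flow-rate coupling, per-wavelength
    pressure rise and friction force (pumping curves), wave-frame stream
    function with trapped-bolus detection and quantification, and an
    independent finite-difference boundary-value oracle that verifies every
    closed form.  Includes delimited-text exporters and a command-line driver
    for the standard parameter studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    grDevices,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
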