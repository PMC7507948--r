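Package: portoflow
Title: Reduced-Order Hemodynamics of the Portal Venous System
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Non-invasive estimation of free portal pressure from Doppler
    ultrasound measurements via a steady laminar (Hagen-Poiseuille) network
    reduction of the incompressible Navier-Stokes equations on the canine
    portal venous tree.  Provides a vessel-tree data model with triangulated
    surface-mesh export (STL/VTK), conversion of Doppler diameter/velocity
    readings into mass-balanced boundary conditions, a direct network
    solver for nodal gauge pressures, a synthetic-cohort generator emulating
    a five-group carbon tetrachloride fibrosis study, and the method-comparison
    statistics used to validate virtual against invasive portal pressure:
    Bland-Altman limits of agreement with confidence intervals, ICC(2,1),
    Lin's concordance correlation, ROC/AUC with DeLong intervals, and
    threshold diagnostics with exact binomial and log-method likelihood-ratio
    intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
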