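Package: aneushear
Title: Hemodynamic Wall-Shear Analysis Pipeline for Cerebral Aneurysm Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the hemodynamic analysis performed downstream of
    image-based computational fluid dynamics of cerebral aneurysms:
    construction and automated tuning of three-element Windkessel (RCR)
    outlet boundary conditions with inverse-area resistance splitting,
    postprocessing of wall-shear-stress vector fields on triangulated
    vascular surfaces into time-averaged wall shear stress (TAWSS),
    oscillatory shear index (OSI) and low-shear-area metrics (LSA,
    MTLSA), mesh-convergence bookkeeping, and matched-pair statistical
    comparison of growing versus stable aneurysms with an exact paired
    Wilcoxon signed-rank test. A synthetic-data module generates
    labeled tube-plus-dome surface meshes, pulsatile inflow waveforms
    and paired cohorts with analytically known ground truth, so the
    whole pipeline can be exercised end to end without a 3D solver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
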