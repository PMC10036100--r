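Package: dosimargin
Title: Physical and Biological Dosimetric Margins for SBRT Prescription Methods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying setup-error robustness of stereotactic body
    radiotherapy (SBRT) dose distributions in physical and radiobiological
    terms. Generates parametric spherical-phantom dose distributions for
    point (isocenter) and marginal (isodose-level) prescriptions, converts
    physical dose to biologically effective dose (BED) voxel-wise with the
    linear-quadratic model, derives physical and biological dosimetric
    margins (PDM/BDM) from isocenter-shift scans under a D95 coverage
    criterion, and fits biological conversion factor (BCF) models that map
    PDM to BDM as a function of dose per fraction and prescription isodose
    level.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
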