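Package: psmapbpk
Title: Whole-Body PBPK Simulation of PSMA-Targeted Radioligand Imaging and Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Physiologically-based pharmacokinetic (PBPK) modelling of
    PSMA-specific radioligands in virtual metastatic prostate-cancer
    patients. Simulates competing radiolabelled ("hot") and unlabelled
    ("cold") ligand with receptor binding, internalization, cellular
    release, renal excretion and physical decay; computes normalized
    activity concentrations for Ga-68 PET imaging and MIRD absorbed doses
    with sphere S-values for Lu-177 therapy; generates seeded virtual
    patient cohorts and sweeps ligand amount, binding kinetics and
    internalization rate to locate optimal tumour-to-kidney dose ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
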