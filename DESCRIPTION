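Package: petdosim
Title: Quantitative Immuno-PET Pharmacokinetics and Radiation Dosimetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for preclinical zirconium-89 immuno-PET
    quantification: framed time-activity curves with decay correction and
    standardized uptake values, single-tissue-compartment perfusion
    estimation from oxygen-15 water with an image-derived input function,
    noncompartmental antibody plasma pharmacokinetics, ex vivo
    biodistribution and autoradiograph normalization, and rabbit-to-human
    residence-time extrapolation with MIRD-style organ absorbed doses and
    ICRP-103 effective dose from a user-supplied S-value matrix. A seedable
    synthetic-data module generates ground-truth inputs for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
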