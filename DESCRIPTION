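Package: srspreplan
Title: Knowledge-Based Pre-Planning of 12 Gy Isodose Volumes for
    Linac-Based Stereotactic Radiosurgery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for knowledge-based pre-planning of single-isocenter,
    linac-based stereotactic radiosurgery (SRS) of small intracranial
    lesions.  Fits a two-stage hierarchical model of the total volume
    enclosed by the 12 Gy isodose surface (TV12) as a function of planning
    target volume (PTV) and prescription dose (PD), separately for
    circular-cone arc therapy (CAT) and dynamic conformal arc therapy
    (DCAT) plans.  Supports prescription-dose rescaling of isodose-volume
    curves, forward prediction of the normal-brain dose metric V12
    (= TV12 - GTV), inverse pre-planning queries (largest PTV or PD
    compatible with a V12 goal), RTOG diameter-based dose guidelines,
    paired CAT-vs-DCAT conformity and low-dose-spread comparison, and a
    synthetic-cohort generator used for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
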