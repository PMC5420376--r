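Package: jointplay
Title: Joint Play Envelope Analysis of Lower-Limb Rotational and Anterior Knee Laxity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing robotic lower-limb axial-rotation laxity tests
    alongside KT-1000 anterior tibial translation in patients after ACL
    reconstruction. Extracts load-deformation curve features (maximum external
    and internal rotation, rotational position and play at 0 Nm of torque,
    endpoint slope) from torque-angle hysteresis recordings, computes the
    composite Joint Play Envelope statistic (total leg rotation times KT
    manual-maximum translation, mm-deg), classifies patients by VAS
    satisfaction, and evaluates biomechanical criteria as diagnostic screening
    tests (sensitivity, specificity, predictive values, exact Fisher p).
    Includes a seeded synthetic-cohort generator with an invertible
    exponential-stiffening hysteresis model, recovery of integer 2x2
    contingency tables from rounded published screening values, paired and
    unpaired group comparisons, pointwise t tests along torque-registered
    curves, and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
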