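Package: beamaudit
Title: Dosimetric Beam-Matching Audit of Linac Photon Beams
Version: 1.0.0
Authors@R:
    person("MedPhys", "Tools", email = "medphys@example.org", role = c("aut", "cre"))
Description: Tools for auditing beam matching between medical linear
    accelerators from water-phantom scan data. Extracts percentage-depth-dose
    parameters (depth of maximum dose, PDD10, R80, quality index) and lateral
    profile parameters (flatness, unflatness, symmetry, penumbra) for
    flattened and flattening-filter-free 6 MV photon beams, including
    inflection-point renormalization of filter-free profiles. Compares
    measured curves against baselines with a one-dimensional gamma index
    under configurable dose-difference/distance-to-agreement criteria,
    computes output factors with field-size-dependent tolerances, and
    aggregates deviation-from-baseline verdicts into machine-readable audit
    reports. Ships a synthetic water-phantom beam generator with closed-form
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
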