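Package: hindpawCT
Title: Seeded-Watershed Segmentation and Longitudinal Bone Morphometry for
    Murine Hindpaw Micro-CT
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Marker-based watershed segmentation of the 30-31 bones of the
    mouse hindpaw from Hounsfield-unit calibrated micro-CT volumes, with a
    segmentation-error taxonomy (oversplit, overconnected, combination) and
    scripted merge/re-split corrections, per-bone volume extraction and
    percent-change-from-baseline morphometry, and two-way ANOVA effect sizes
    (eta-squared, partial eta-squared, omega-squared) for ranking bones as
    longitudinal imaging biomarkers of inflammatory-erosive arthritis. A
    synthetic hindpaw phantom generator with programmable per-bone, per-group
    erosion trajectories provides ground truth for validation at desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
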