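Package: apart
Title: Automated Per-Fraction Plan Checks for Online-Adaptive MR-Guided
    Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares an original and an on-table-adapted radiotherapy
    treatment plan (DICOM RT Plan plus RT Structure Set pairs) and runs a
    battery of per-fraction quality-assurance checks: patient and plan
    identity, structure-set integrity (deleted structures, missing slices,
    volume differences), consistency of GTV/CTV/PTV margin expansions with
    sphere-equivalent expansion radii, electron-density overrides, and
    multi-leaf-collimator modulation complexity (segment areas, subsegment
    counts, effective monitor units). Alerts are weighted and aggregated
    into a traffic-light verdict with a detailed JSON or text report. A
    fixture generator writes valid synthetic DICOM pairs with injectable
    faults so every check is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
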