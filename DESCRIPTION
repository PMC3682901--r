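Package: rtrecur
Title: Recurrence Analysis for Radiotherapy Follow-Up Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automated pattern-of-failure analysis for radiotherapy.
    Registers follow-up CT series to the planning CT with mutual-information
    rigid registration (with pre-initialization for heavily rotated
    acquisitions), voxelizes delineated structures with subvoxel accuracy,
    computes dose-volume histograms and descriptive dose statistics of a
    segmented recurrence volume against separate base and boost plans, and
    classifies the recurrence location relative to the boost volume, its
    margin-expanded shells and the 80 percent isodose volume. Includes a
    geometric phantom generator that writes genuine DICOM CT, RT Structure
    Set and RT Dose files with analytically known answers, so the full
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
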