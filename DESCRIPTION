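Package: hifutrack
Title: Lesion Tracking and Focus Planning for Image-Guided Focused Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for intraoperative ultrasound guidance of high-intensity
    focused ultrasound (HIFU) therapy. Implements morphological active
    contours without edges (MACWE) for real-time lesion tracking with a
    large single structuring segment that ignores fine internal structure,
    speckle-aware frame preprocessing, mutual-information monitoring of
    unexpected patient movement with normalized cross-correlation contour
    correction, automatic sonication-focus planning over the tracked
    lesion, overlap and boundary-distance evaluation metrics, and a
    speckle phantom simulator that provides ground-truth sequences for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    yaml,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
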