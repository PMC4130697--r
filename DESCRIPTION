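Package: avrot
Title: Axial Vertebral Rotation from Antero-Posterior Radiograph Landmarks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures axial vertebral rotation on antero-posterior spine
    radiographs from annotated landmarks (vertebral body corners and pedicle
    inner contours) using a planar geometric construction based on the shared
    dimensional proportions of thoracic and lumbar vertebrae. Includes a
    digital analogue of a vertebral rotation device: a parametric 3-D
    vertebra projected to AP landmarks at known rotation, with rater noise
    and wedge-deformity controls, so the method's accuracy can be verified
    end-to-end without imaging data. Provides recovery statistics across
    simulated raters, the small-angle (tan alpha ~ alpha) error table,
    Nash-Moe grading as a comparator, a YAML landmark-file format, SVG
    construction overlays, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    yaml,
    stats,
    tools,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    xml2
Config/testthat/edition: 3
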