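Package: spraysim
Title: Desk-Scale Simulator for Vision-Guided Precision Spot Spraying
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates the control loop of a camera-guided precision
    sprayer working broadcast-seeded crop rows: synthetic plant fields
    with ground-truth weed and crop positions, an emulated per-frame
    detection stream with tunable miss, misclassification and clutter
    rates, frame-to-frame bounding-box association with vision-based
    ground-speed estimation, spray-schedule queuing with footprint-based
    clearing of redundant schedules, and an evaluation suite covering
    targeting precision/recall, wrong- and non-targeting rates,
    spray-volume reduction accounting, nozzle footprint geometry and
    PASCAL VOC 2007 detection metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
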