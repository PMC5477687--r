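Package: thermoroi
Title: Infrared Thermography Quantification of Brown Adipose Tissue Activation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify brown adipose tissue (BAT) activation from
    infrared thermography video of the cervical-supraclavicular region.
    Detects the "hot" region of interest in each frame with a modified
    seeded-region-growing segmentation, calibrates pixel coordinates to
    metric body-surface coordinates from four cool fiducial disks via a
    3x3 planar homography, converts sequence-averaged region area and
    temperature to radiated power with the Stefan-Boltzmann law, and
    classifies subjects into low/high-BAT responder groups. Includes a
    synthetic thermogram generator with ground truth so that the whole
    pipeline is testable without human data, plus portable readers and
    writers for temperature-frame sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    tiff,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
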