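Package: nodulecad
Title: Computer-Aided Detection of Stiff Nodules in Soft-Tissue Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates and analyses robotic palpation scans of agar
    tissue-mimicking phantoms containing stiff spherical inclusions.
    Provides a phantom model with mechanical and acoustic material
    properties, a scan simulator producing camera images,
    force-controlled indentation traces and 16 MHz pulse-echo
    ultrasound A-scans on a regular indentation grid, vision utilities
    (background subtraction, orientation normalisation, grid
    generation), per-point stiffness and Correlation Index Amplitude
    features, unsupervised fuzzy c-means labelling with AND/OR sensor
    fusion, and confusion-matrix evaluation against the known inclusion
    layout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    stats,
    utils,
    yaml
Suggests:
    e1071,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
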