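Package: multivein
Title: Multi-Finger Vein Recognition and Contactless Hand-Imaging Geometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for contactless multi-finger vein biometrics: thin-lens
    depth-of-field and field-of-view computations for acquisition geometry,
    clap-coded frame synchronization, calibrated stereo rectification with
    disparity-to-depth conversion, photometric-stereo surface-normal estimation
    with flat-field correction, four-finger hand segmentation with anatomical
    reordering and rotation normalization, maximum-curvature vein template
    extraction, translation-searched cross-correlation template matching,
    FMR/FNMR/HTER protocol evaluation with dev-to-eval threshold transfer, and
    RBF-SVM finger-score fusion. Includes seeded synthetic generators (NIR hand
    renders with ground-truth vein networks, stereo pairs, Lambertian
    photometric-stereo quadruples) so every stage is testable without access to
    restricted biometric data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    e1071,
    jsonlite,
    yaml,
    png,
    tiff,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
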