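Package: eusTracker
Title: Hardware-Free Endoscopic Ultrasound Probe Tracking by Haar-Feature
    Dictionary Matching
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Localizes an endoscopic ultrasound (EUS) imaging plane inside a
    3D CT/MRI-like volume without external tracking hardware. A dictionary of
    B-mode ultrasound images is simulated over a grid of candidate probe
    poses using a convolution-model simulator driven by point-scatterer
    phantoms; every image is encoded as a multi-scale Haar-like feature
    vector via integral images, and a target EUS frame is localized by
    maximizing the per-scale-averaged normalized cross-correlation against
    the dictionary. Includes geometric and bitmap scatterer-phantom
    generators, oblique slice extraction from volumes, linear and
    curvilinear array presets with scan conversion, pose-grid builders for
    phantom and patient-MRI schemes, and marker-based localization-error
    evaluation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    RNifti,
    png,
    tiff,
    jsonlite,
    yaml,
    EBImage
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, BiomedicalInformatics, Visualization
RoxygenNote: 7.3.3
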