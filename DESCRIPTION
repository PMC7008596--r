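Package: aoctair
Title: Airway Volumetry from Endoscopic Anatomical Optical Coherence
    Tomography with CT Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for evaluating endoscopic anatomical optical coherence
    tomography (aOCT) as a volumetric modality for the nasal airway and the
    internal nasal valve. Provides a synthetic nasal-airway phantom
    generator, a helical pullback scan simulator with range fold-over,
    sensitivity roll-off dropout, first-surface shadowing and nonuniform
    rotational distortion (NURD), polar-frame contour segmentation and 3-D
    lumen reconstruction, airflow-perpendicular CT resampling and
    threshold segmentation, cross-sectional-area profiling with
    minimum-CSA valve localization, rigid surface registration (ICP),
    field-of-view clipping, and Dice/Hausdorff comparison metrics,
    together with an embedded cadaveric study table and its summary
    statistics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
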