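Package: aortax
Title: Quantitative Aortic Morphometry from Segmented CT Angiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-segmentation analysis of contrast-enhanced CT angiography
    of the aorta. Starting from a Hounsfield-unit volume and a co-registered
    multi-organ label map, the package refines the aortic label into pure
    contrast-enhanced lumen and calcified plaque with adaptive Hounsfield
    thresholds, extracts a medial centerline with regularized local frames,
    straightens the vessel by curved planar reformatting, detects anatomical
    landmarks (ventricular-aortic junction, aortic arch boundaries, diaphragm,
    renal level, and the aortic-root landmarks), partitions the centerline into
    the standard anatomical segments, and reports per-segment maximal
    diameters, cross-sectional areas, tortuosity indices and a calcification
    ratio, with quality-control safeguards for incomplete or non-contrast
    scans. A synthetic vascular phantom generator with analytic ground truth
    makes every stage testable without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    grDevices,
    graphics,
    utils,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
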