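Package: nemaiq
Title: Automated Sphere Localization and ROI Analysis for the NEMA NU-2
    Image Quality Phantom
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated analysis of PET/CT scans of the NEMA NU-2 Image
    Quality phantom. Binary matched-filter templates locate the six hot
    spheres, starting with a coarse PET detection of the three largest
    spheres, followed by accurate sub-voxel CT localization with air-bubble
    compensation, hexagonal extrapolation to the small spheres, a
    three-point initial CT-to-PET isometry, and a six-degree-of-freedom
    perturbation search refined by a six-dimensional quadratic fit.
    Reports sphere centers, spherical ROI statistics, and PET/CT
    misalignment diagnostics. Includes a synthetic phantom generator and a
    minimal DICOM series reader/writer so the whole pipeline is testable
    without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
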