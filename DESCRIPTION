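Package: locorigid
Title: Locally Rigid Matching and Comparative Visualization of Longitudinal 3D Body MR Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: One-click locally rigid matching of baseline and follow-up 3D
    body-MR volumes. Given two co-registered scans and a precomputed dense
    deformation field, a single seed point drives confidence-connected region
    growing, point-pair extraction from the deformation field, a closed-form
    unit-quaternion (absolute orientation) rigid fit, and rigid resampling of
    the follow-up volume into baseline space. Includes comparison
    visualizations (orange-blue color fusion, radial uncertainty iso-contours,
    deformation sphere, magic-lens composite), MetaImage and NIfTI volume and
    vector-field input/output, and a synthetic articulated phantom with known
    ground-truth per-bone rigid transforms for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    png,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
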