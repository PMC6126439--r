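Package: respimoco
Title: Surrogate-Driven Respiratory Motion Correction for PET/MR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale simulation and reconstruction toolkit for
    surrogate-driven respiratory motion correction in simultaneous PET/MR.
    Provides a breathing thorax phantom with known ground-truth deformation,
    time-binned PET acquisition and dynamic-MR simulation, a PET-derived
    respiratory surrogate with PET/MR clock alignment, a per-voxel
    two-surrogate linear motion model fitted robustly to slice
    registrations, gated motion-compensated OSEM reconstruction with
    per-gate warped attenuation maps, and a lesion quantification layer
    (SUVpeak, SUVmax, reader-score statistics with exact Wilcoxon
    signed-rank and paired t tests).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    signal,
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
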