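Package: mpileak
Title: Quantification of Pulmonary Vascular Leakage from Co-Registered
    Magnetic Particle and Micro-CT Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation, co-registration, segmentation and quantification of
    paired magnetic particle imaging (MPI) and micro-CT volumes of the mouse
    thorax. Provides a digital torso phantom with known tracer leakage,
    fiducial-based closed-form rigid registration, Hounsfield-threshold lung
    and body segmentation, the SPIO extravasation index (SEI; lung-to-body
    signal ratio normalised by lung volume, units 1/cm^3), tracer linearity
    calibration, Evans blue standard-curve inversion, and exact Mann-Whitney
    group comparison, so the whole in vivo leakage-quantification workflow
    can be exercised and validated without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
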