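Package: phantom4D
Title: Four-Dimensional Digital MRI Phantom for Liver Motion Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds a four-dimensional computerized abdominal MRI phantom for
    liver motion studies. A parametric anatomy builder emits a labeled
    reference anatomy at end of exhalation; synthetic T1-like MR texture is
    composited per structure category (deformable texture mapping for key
    organs, iterative patch-based pattern generation for large soft-tissue
    volumes, uniform intensity with Rayleigh noise for air-filled structures,
    per-phase uniform assignment for bone); a hypointense spherical tumor is
    inserted in the liver; and the reference volume is warped through a
    respiratory cycle via deformation vector fields (synthesis, morphological
    repair, fixed-point inversion, tricubic warping) to emit 10-phase 4-D
    series for three breathing presets. Includes mask-driven Demons deformable
    registration, tumor segmentation and center-of-mass kinematics metrics,
    and NIfTI-1/MetaImage input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    Rcpp,
    RNifti,
    yaml,
    jsonlite,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    oro.nifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
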