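Package: cbmap
Title: Cortical Bone Mapping of Vertebral CT with an Endocortical Slope Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Model-based deconvolution of calibrated quantitative CT (QCT)
    density profiles sampled perpendicular to a vertebral surface mesh,
    using a piecewise cortex model with a linearly decreasing endocortical
    transition. Produces per-vertex maps of cortical thickness (Ct.Th),
    endocortical thickness (Ec.Th), cortical and cancellous bone mineral
    density (Ct.BMD, Cn.BMD) and cortical mass surface density (CMSD),
    registers them onto a canonical shape, and performs permutation-based
    statistical parametric mapping of longitudinal changes. Includes a
    synthetic phantom and two-timepoint cohort generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    RNifti,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
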