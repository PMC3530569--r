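Package: planarpet
Title: Symmetry-Compressed OSEM Reconstruction for Dual-Head Planar PET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Iterative image reconstruction for dual-head planar positron
    emission tomography (PET) scanners. Implements a symmetry-compressed
    sparse system response matrix: detector response functions are computed
    once for a small pool of seed voxels (one per z-plane reflection class
    and in-plane offset class) and expanded on the fly through shift
    invariance, reflection symmetries and axis interchangeability. On top of
    the compressed matrix the package provides deterministic forward and back
    projectors organised as shift-invariant line-of-response families,
    MLEM/OSEM reconstruction with orientation-based subsets, a micro Derenzo
    resolution phantom simulator with Poisson noise, and file formats (NIfTI
    volumes, Matrix Market seed pools, dense and sparse histograms) plus a
    command-line interface tying the pipeline together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
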