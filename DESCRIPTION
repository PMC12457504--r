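Package: ringhomog
Title: Image-Based Hygro-Elastic Homogenization of Wood Growth Rings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes effective hygro-elastic properties of cellular plant
    tissue (oak-like growth rings) from 3D voxel images. Provides a synthetic
    growth-ring phantom generator with exact ground truth, level set-based
    two-phase segmentation with a hybrid global/local intensity energy, a
    signed-distance orientation field for orthotropic cell-wall material
    frames, a Heaviside-enriched XFEM discretization on a structured
    hexahedral mesh with moment-fitting quadrature for cut elements, periodic
    asymptotic-homogenization cell problems solved by a preconditioned
    conjugate-gradient method with an element-sum spectral pseudo-inverse
    preconditioner, and reconstruction of local strain and stress fields
    under free and constrained moisture expansion.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
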