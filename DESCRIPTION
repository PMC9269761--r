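Package: hbgvf
Title: Active Contour Segmentation with Hessian-Based Gradient Vector Flow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parametric active-contour (snake) segmentation of 2-D grayscale
    images driven by gradient-vector-flow external force fields.  Implements
    the Hessian-based gradient vector flow (HBGVF), an anisotropic diffusion
    of the edge-map gradient steered by a per-pixel tensor built from the
    eigen-structure of the image Hessian, alongside five classic comparator
    fields (GVF, GGVF, VEF, NGVF, CN-GGVF), a semi-implicit snake solver,
    synthetic benchmark scenes with analytic ground-truth boundaries, and a
    small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
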