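Package: curvetrack
Title: Reconstruction of Cell and Particle Tracks on Curved Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping 3D cell- and particle-tracking data that move
    on hidden curved surfaces onto faithful 2D representations. Implements a
    two-pass surface "unwrapping" algorithm based on slice-wise ellipse
    fitting, and Riemannian (metric) manifold learning in which a
    position-dependent 2x2 metric tensor is estimated from a
    density-renormalized graph Laplacian on a locally linear embedding.
    Includes a biased-persistent random-walk simulator on parametric surfaces
    for ground-truth validation, and unbiased directional statistics (bias
    angles, persistence angles, straightness index) together with
    deviation-distance comparisons across projection methods.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    methods,
    Matrix,
    igraph
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
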