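Package: zernike3d
Title: Vectorized 3D Zernike Moments for Protein Shape Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A batched engine for 3D Zernike moments of protein shapes.
    Converts C-alpha point clouds read from PDB or mmCIF files into density
    grids with a Gaussian mixture, computes complex Zernike moments up to
    order 40 through a precomputed log-space coefficient cache and a sparse
    geometric-moment contraction, derives rotation-invariant shape
    descriptors and volumetric similarity scores, and performs structural
    superposition by Canterakis normalization of the moments: alternative
    moment sets are generated from the principal second-order frame, the
    best cross-structure pair is selected by dot product, and a 4x4
    homogeneous transform is returned.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
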