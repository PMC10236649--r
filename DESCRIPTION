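Package: bonatlas
Title: Unbiased Bone Shape Templates and Automatic Surgical Landmark Propagation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the feasibility of automatic surgical planning from
    average population shape models of long bones. Provides a synthetic humerus-like
    mesh population generator with known latent deformation modes and carried-along
    ground-truth landmarks; STL/landmark/volume input and output with mesh-volume
    conversion; rigid iterative-closest-point, affine and regularized demons-style
    deformable registration engines; iterative unbiased groupwise template
    construction plus a correspondence mean-shape comparator; PCA explained-variance
    evaluation of transferred landmark point clouds and signed surface-distance
    models; and held-out validation of atlas-based landmark propagation by RMSE,
    paired t-tests and percent improvement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
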