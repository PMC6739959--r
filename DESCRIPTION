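Package: MorphoIntegr
Title: Landmark-Based Morphometrics and Phenotypic Integration
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for 2D landmark-based geometric morphometrics and the
    analysis of phenotypic integration and disparity, with phylogenetically
    informed counterparts. Implements generalized Procrustes superimposition
    with semilandmark sliding under minimum bending energy or minimum
    Procrustes distance, thin-plate-spline interpolation with bending-energy
    spectra, partial warps and Jacobian log-determinant deformation fields,
    between-group principal component analysis, residual-randomization
    permutation (RRPP) linear models including Procrustes ANOVA, evolutionary
    allometry and Procrustes-variance disparity, two-block partial least
    squares with integration effect sizes and major-axis comparisons,
    Bookstein's global (intrinsic) integration regression, multivariate
    phylogenetic signal (Kmult), phylogenetic Procrustes ANOVA and
    phylogenetic PLS under Brownian motion, and a synthetic-data generator
    emulating a two-lifestyle, two-structure comparative study design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ape,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
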