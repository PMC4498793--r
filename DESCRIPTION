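Package: cortmorph
Title: Cortical Morphometry from Neonatal Tissue Label Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantification of cortical morphology from 3D tissue-label
    volumes of the developing brain: tissue volumes, configuration-weighted
    voxel surface area, Laplace-equation (streamline) cortical thickness,
    convex-hull gyrification index, and a normalized global mean-curvature
    folding measure, computed whole-brain and per lobe, with longitudinal
    increase factors and linear mixed-model cohort statistics. Includes a
    parametric folded two-shell brain phantom generator with quadrature
    ground truth and a two-timepoint synthetic cohort generator for
    validation of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    lme4,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
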