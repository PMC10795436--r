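Package: organmatch
Title: Organ-Contour-Driven Auto-Matching for Image-Guided Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rigid soft-tissue positioning for image-guided radiotherapy
    driven by organ surface meshes. Implements a weighted vertex-to-surface
    cost over daily cervix and uterus models, a step-halving (dichotomy)
    translational and rotational positioning optimizer with couch-accuracy
    step floors and an optional rotation clamp, isotropic and anisotropic
    planning-target-volume (PTV) margin expansion, and a vertex-based PTV
    coverage metric. Ships a synthetic pelvic phantom generator with known
    ground-truth displacements so every stage is testable without patient
    data, plus cohort-level summaries and paired scenario comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
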