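Package: vertecol
Title: Ecological Inference from Vertebral Shape in Carnivorans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A 3D geometric-morphometrics pipeline for inferring locomotor
    ecology (running speed, hunting mode) from serially sampled presacral
    vertebrae. Implements generalized Procrustes superimposition, principal
    component analysis of shape, multi-block combination of serially
    homologous elements, distance-based PERMANOVA with pairwise tests,
    multivariate phylogenetic generalized least squares under Brownian
    motion with residual-randomization significance, canonical variate
    analysis with Mahalanobis membership probabilities for projecting fossil
    configurations into an extant morphospace, and a synthetic landmark-data
    generator with known phylogenetic and ecological structure for
    download-free testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
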