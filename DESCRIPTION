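Package: connscale
Title: Scaling of Modular Organization and Communication Efficiency in
    Mammalian Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to study how the modular organization and communication
    efficiency of weighted, spatially embedded brain networks scale with
    brain volume across a cohort of animals. Implements multiresolution
    consensus community detection (Louvain across a logarithmic resolution
    sweep, co-classification matrices and consensus partitions), three
    network communication models (shortest-path efficiency, search
    information and communicability) with a lattice/random-standardized
    communication morphospace, network portrait divergence for
    representative-network selection and outlier screening, geometry- and
    degree-preserving null models, bootstrapped log-log allometric scaling
    fits, and a synthetic cohort generator of distance-dependent modular
    connectomes for end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
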