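Package: suturefe
Title: Finite-Element Analysis of Cranial Suture Mechanics on Synthetic Skull Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying how patent cranial sutures modify bone strain
    under bite loading. Generates parametric multi-tissue tetrahedral "skull
    phantom" meshes (cortical and trabecular bone, straight and interdigitated
    suture bands, tooth pegs with periodontal-ligament sleeves), assigns
    linear-elastic tissue properties with sutured and fused variants, converts
    muscle architecture to maximal isometric forces via physiological
    cross-sectional area, distributes those forces as direct strands and
    frictionless wrapped paths, solves the static linear-elastic problem on
    4-node tetrahedra, cross-checks bite reactions against a determinate
    rigid-body statics model, and post-processes principal strain fields with
    virtual strain gauges, per-bone surface summaries, difference fields and
    legacy-ASCII VTK export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    yaml,
    readr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
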