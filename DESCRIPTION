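Package: habnet
Title: Pollution Gradients, Microbial Communities and Association
    Networks in Mosquito Larval Habitats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for field surveys of container-breeding
    mosquito larval habitats along urban pollution gradients. Computes
    proximity-based pollution variables for community gardens, preprocesses
    amplicon OTU count tables (contaminant and rare-taxon filtering,
    rarefaction, alpha and beta diversity), runs the abiotic-gradient
    ordination chain (PCA, PERMANOVA, distance-based redundancy analysis,
    Spearman screening, Procrustes Monte Carlo concordance), filters
    untargeted LC-HRMS feature matrices through a quality-control cascade,
    and infers mixed-type association networks from robustly binarized
    variables using Zhang's association-rule score with an exact binomial
    edge test. Ships seeded synthetic-data generators that emulate paired
    colonized/noncolonized samples so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    permute,
    stats,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
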