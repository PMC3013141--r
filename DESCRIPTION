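Package: hydroxsite
Title: Prediction of Protein Hydroxylation Sites from Sequence Windows
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sequence-based prediction of hydroxyproline and hydroxylysine
    sites. Encodes 13-residue windows around candidate proline or lysine
    residues into a named feature space built from AAindex physicochemical
    indices, PSI-BLAST position-specific scoring matrix (PSSM) conservation
    scores and per-residue intrinsic-disorder scores; ranks features by
    maximum relevance (MaxRel) and minimum-redundancy maximum-relevance
    (mRMR) mutual-information criteria; selects an optimal feature subset by
    incremental feature selection with a cosine-distance nearest-neighbour
    classifier under jackknife (leave-one-out) cross-validation; and reports
    sensitivity, specificity, accuracy and the Matthews correlation
    coefficient together with feature-distribution analyses. Includes a
    synthetic-fixture generator with planted informative features so the
    whole pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
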