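Package: micatype
Title: Two-Type Classification of MICA Alleles and Downstream NKG2D
    Functional Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Partitions human MICA protein variants into the two functional
    types defined by a six-linked-site amino-acid signature (positions 36,
    129, 173, 206, 210 and 215 of the mature protein) and quantifies the
    functional consequences of the partition: grouped antibody and NKG2D-Ig
    reactivity on Luminex single-antigen-bead panels, the concentration at
    which NKG2D reporter-cell activation crosses 50% GFP-positive (EC50),
    NK-cell killing efficiency across effector-to-target ratios, and
    Hardy-Weinberg carrier coverage from population allele-frequency tables.
    Ships a transcription of the published 29-allele polymorphic-site
    alignment and seeded generators that emulate each assay, so the whole
    pipeline runs and is testable without wet-lab data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
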