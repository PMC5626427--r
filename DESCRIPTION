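Package: octsector
Title: Axonal-Tract-Dependent Macular Sectors for Structural Glaucoma Progression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives axonal-tract-dependent macular sectors from grid-point-wise
    Spearman correlation between OCT macular layer thickness (mRNFL, mGCIPL) and
    temporal circumpapillary RNFL clock sectors, then detects structural glaucoma
    progression per sector and hemifield with trend (normative slope comparison)
    and event (two-exam baseline with confirmation) analyses, and compares both
    against a pointwise-regression visual-field progression classification on the
    central 16 points of the 24-2 grid. Includes a synthetic longitudinal cohort
    generator with arcuate-bundle-linked thinning and full ground truth, tidy
    result tables, and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
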