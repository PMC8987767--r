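Package: cytovag
Title: Rule-Based Classification of Exfoliated Canine Vaginal Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for standardized evaluation of canine vaginal smears.
    Implements a deterministic flowchart classifier for exfoliated vaginal
    epithelial cells (parabasal, intermediate, superficial, squamous) driven
    by cell diameter, cornification-line count and nuclear morphology, with
    the quantitative thresholds used in the veterinary literature. Includes
    percentile-based threshold calibration from nucleus-area measurements,
    Fleiss' kappa inter-rater agreement with interpretation bands, estrous
    cycle staging from smear composition under selectable literature rule
    sets, a seeded synthetic smear generator (feature tables and rendered
    images with ground-truth masks), and a morphometry module that measures
    cell records from smear images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    generics,
    ggplot2,
    jsonlite,
    tools,
    yaml,
    png,
    tiff,
    EBImage,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
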