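Package: ctcmorph
Title: Morphometry of Circulating Tumor Cells from Immunofluorescence
    Thumbnail Galleries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures DAPI, cytokeratin (CK) and CD45 signals of
    expert-marked events in CellSearch-style cartridge image galleries,
    classifies event singularity by the normalized perimeter-to-area (P2A)
    shape ratio, applies the nested single-CTC / intact-nucleus selection
    cascade, converts areas to equivalent-circle diameters, computes
    nucleus-to-cytoplasm ratios, and compares cohorts with nonparametric
    rank tests. Includes a synthetic cartridge generator with known ground
    truth so every stage of the pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
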