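Package: beelca
Title: Composite-Sample Bee Metabarcoding with Windowed Lowest-Common-Ancestor Assignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for identifying wild bee genera from composite tissue
    samples (pooled bee legs) sequenced at the CO1 Folmer barcode locus.
    Implements the full metabarcoding workflow: primer binning and quality
    trimming of paired reads, scaffolding or merging into templates, greedy
    centroid clustering with abundance grafting and crosstalk censoring,
    contaminant and chimera screening, taxonomic assignment by lowest common
    ancestor over a score window with identity-based rank demotion, and
    genus-level counts tables. Includes a curated-reference-database builder,
    a ground-truthed composite-vial simulator, and concordance statistics for
    comparing metabarcoding detections with morphological identifications and
    Sanger-sequenced positive controls.
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
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    withr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
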