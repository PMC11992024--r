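Package: livmet
Title: Spatial Co-Localization, Neoantigen Ranking and TCR Clonotype
    Analysis for Liver-Metastasis Immunotherapy Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for in-situ transcriptomic and immunogenomic
    readouts of liver-metastasis immunotherapy experiments. Implements a
    transcript-level pairwise co-localization score for MERFISH/MERSCOPE
    detected-transcript tables (fixed-radius proximity counting with
    same-cell exclusion and a unique-interaction rule, normalized per gene
    pair) together with differential condition matrices and heatmaps;
    consensus filtering, score integration, ranking and chimeric-construct
    assembly for neoantigen candidates; TCR clonotype expansion classing and
    tissue-sharing summaries; and closed-form quantifications (vector copy
    number from droplet digital PCR, caliper tumor volume, and a gene
    signature score with median stratification for survival analysis).
    Seeded synthetic-data generators emulate every input so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
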