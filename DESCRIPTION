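Package: tamtalk
Title: Macrophage-GBM Ligand-Receptor Crosstalk Inference from Conditioned-Media Proteomics and Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers tumor-associated macrophage (TAM) secreted drivers of
    glioblastoma invasion by integrating conditioned-media label-free
    proteomics with bulk and single-cell transcriptomics. Provides
    replicate-detection filtering and M2/M1 fold-change summaries of
    protein intensity tables, secretome restriction via a predicted-secreted
    annotation, receptor-expression-gated construction of ligand-receptor
    interaction records with macrophage polarization-specificity classes,
    single-cell cluster enrichment (pct.1/pct.2) based ligand
    prioritization including microglia versus bone-marrow-derived TAM
    ontogeny calls, a seeded synthetic-data generator with planted ground
    truth for end-to-end testing, and a configurable pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
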