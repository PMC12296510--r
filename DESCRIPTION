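Package: pptarget
Title: Calling Serine/Threonine Phosphatase Target Sites from Quantitative Phosphoproteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for identifying protein phosphatase
    (PP1/PP2A-type) target phosphosites from quantitative phosphoproteomic
    intensity tables. Implements localization-probability and intensity-floor
    filtering, two-tier missing-value imputation (iterative low-rank SVD
    completion per condition followed by per-column downshifted-normal draws),
    optional normalization of phosphosites to source-protein abundance,
    pooled-variance differential testing with Benjamini-Hochberg or
    permutation FDR, inhibitor-protection call logic, set algebra over calls
    from in vitro and in vivo experiments to derive bona fide target sets,
    phosphosite-window motif and preference (enrichment) matrices, and short
    linear motif (SLiM) scanning with exact dynamic-programming p-values plus
    spacer-geometry and disorder classification of docking-motif hits. A
    synthetic-data module generates proteomes, disorder tracks, and intensity
    tables with known ground truth so every stage is testable without
    deposited mass-spectrometry data.
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
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
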