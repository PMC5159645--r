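Package: rnasa
Title: Sequence-Based Prediction of RNA Solvent Accessibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts per-nucleotide solvent-accessible surface area (ASA) of
    RNA from sequence alone or from an alignment-derived profile using windowed
    support-vector regression, and computes the ground truth it is trained on:
    a Shrake-Rupley numerical ASA over RNA 3D coordinates with a completeness
    filter for residues with missing atoms. Includes alignment profile
    construction with asymmetric pseudocounts, one-hot and profile window
    encoders, chain-level cross-validation and grid search, evaluation metrics
    (pooled and per-base Pearson correlations, density tables), and downstream
    genome analyses: DMS reactivity normalization against a denatured control,
    minor-allele-frequency bin association, and transcript-boundary ASA
    profiles. A synthetic-fixture generator emulates every input class with
    planted, recoverable structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    rlang,
    readr,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    bio3d,
    Biostrings,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
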