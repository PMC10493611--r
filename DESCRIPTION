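Package: stromatlas
Title: Curation and Quantification of Chloroplast Stromal Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for turning shotgun-proteomics search-engine exports into a
    curated organellar proteome compendium. Builds a consensus
    protein-localization Atlas from multiple subcellular predictors plus the
    plastid-genome protein complement, applies spectral-evidence
    inclusion/exclusion rules with database- and prediction-based retention
    exceptions, partitions retained proteins into stromal versus co-isolating
    proteins, estimates relative molar abundance with the exponentially
    modified protein abundance index (emPAI) from in-silico tryptic digests,
    assigns membrane and thylakoid-lumen sub-compartment calls by predictor
    consensus, and compares the resulting proteome against reference protein
    sets. Includes a synthetic-data generator with known ground truth so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
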