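Package: iomrm
Title: Fit-for-Purpose Characterization of Multiplexed Immuno-MRM Assay Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing multiplexed peptide immunoaffinity
    enrichment + multiple reaction monitoring (immuno-MRM) assay panels from
    transition-level peak-area reports. Implements stable-isotope-dilution
    quantification (transition summation, interference screening, light/heavy
    peak-area ratios), response-curve fitting with empirical LLOQ/ULOQ rules,
    intra-/inter-assay precision and stability figures of merit, sequential
    multi-panel enrichment concordance, cohort detection profiling with
    minimum-input extrapolation, rule-based proteotypic peptide selection with
    an additive hydrophobicity index, and a seeded synthetic-data generator
    that emulates the standard fit-for-purpose validation designs.
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
    utils
Suggests:
    Biostrings,
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
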