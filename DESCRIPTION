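Package: proxirank
Title: Ratiometric Ranking and Developmental Dynamics for Antibody-Targeted Proximity-Labeling Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for antibody-targeted proximity-labeling
    proteomics of the axon initial segment (AIS). Reads MaxQuant-style
    proteinGroups tables, applies decoy/contaminant and unique-peptide
    filters, and implements three quantitative branches: dimethyl H/L
    ratio pair analysis with replicate-coverage and negative-control
    cutoffs; 10-plex TMT multi-reference enrichment ranking with median
    normalization, per-reference ranks and top-N overlap; and bridged
    two-plex developmental dynamics with anchor-protein normalization,
    change filtering, profile clustering and volcano statistics. Also
    provides the image-quantification formulas used for validation
    (corrected mean fluorescence, specificity and polarity ratios,
    line-profile periodicity) and a synthetic-data generator with ground
    truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
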