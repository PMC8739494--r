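Package: suscept
Title: Genome-Wide UV Lesion Susceptibility Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of how loss of the RB1 tumor suppressor redistributes
    susceptibility to UV-induced cyclobutane pyrimidine dimer (CPD) lesions
    across the genome. Provides binned lesion-susceptibility tracks and KO/WT
    log2 fold changes, chromatin-state aggregation, random-region resampling
    nulls for pericentric and subtelomeric enrichment, observed/expected
    peak-overlap chi-squared tests, Hi-C A/B compartment metaprofiles with
    bootstrap confidence intervals, repeat-family fractional read assignment
    and differential testing, melanoma mutation-rate and co-occurrence
    statistics (log2 odds ratio, Fisher exact, Benjamini-Hochberg), telomere
    content estimation from reads, and qPCR delta-delta-Cq calculators with
    error propagation. A synthetic-data module generates all pipeline inputs
    with known ground truth for calibration and recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    Biostrings
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
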