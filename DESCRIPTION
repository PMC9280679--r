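Package: granulosig
Title: Granulocyte Transcriptome Signatures of Sepsis Versus Sterile Inflammation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for CD15-positive granulocyte expression profiles
    that distinguish sepsis from non-infectious systemic inflammation (SIRS).
    Implements three-group differential expression with Benjamini-Hochberg FDR
    control, rank-based gene-set enrichment with a permutation null, three
    candidate-selection strategies for validation shortlists, multiplex
    bead-array (QuantiGene-Plex-style) normalization and confirmation/validation
    statistics with exact Mann-Whitney tests and Bonferroni adjustment,
    granule-compartment signature scoring, and granulocyte-precursor blood-count
    comparisons with PCA. A synthetic-cohort generator models bulk CD15
    expression as composition-weighted mixtures of maturation-stage programs
    (promyelocyte through segmented neutrophil) with group-specific precursor
    expansion, providing ground truth for end-to-end recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
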