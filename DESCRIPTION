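Package: MotifContrast
Title: Comparative Analysis of Homologous Structured RNA Motif Alignments
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing two homologous structured-RNA motif
    alignments, such as a riboswitch class and a candidate variant with
    altered ligand specificity. Reads annotated Stockholm alignments
    (consensus secondary structure with pseudoknot layers, per-sequence
    gene-context, phylum and environment tags), builds per-column
    consensus conservation models with mutual-information covariation
    statistics (average product corrected), maps columns between two
    models by profile-profile alignment, detects discriminating features
    (strict and high identity contrasts, presence/absence of structural
    elements), quantifies gene-context and environment associations with
    exact tests, classifies sequences into either motif by profile
    log-odds scoring with a feature vote, and quantifies in-line probing
    binding curves, transcription termination product ratios and
    DTNB-based acetylation calibrations. A seeded synthetic-data
    generator emulates all required input structure so the full analysis
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    Biostrings,
    jsonlite,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Software, SequenceMatching, MultipleSequenceAlignment,
    MotifDiscovery, Classification
RoxygenNote: 7.3.3
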