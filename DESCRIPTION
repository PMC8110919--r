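Package: piwas
Title: Proteome-Wide Antigen Discovery from Random-Peptide Serum Antibody Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a Protein-based Immunome Wide Association Study
    (PIWAS) pipeline for serum epitope repertoire data. Starting from
    per-sample sets of antibody-selected random 12-mer peptides, the package
    computes 5-mer and 6-mer enrichments against an amino-acid composition
    background, z-normalizes them to a control cohort, tiles normalized
    enrichments onto an arbitrary proteome with a smoothed sliding window to
    obtain per-sample per-protein scores and epitope locations, and ranks
    proteins by case-versus-control statistics (outlier sum with a
    permutation null, Mann-Whitney U, Kolmogorov-Smirnov, Hedges' g,
    locational KS, Benjamini-Hochberg FDR). A synthetic-cohort simulator
    with planted epitopes and magnitude/prevalence power experiments is
    included.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    data.table,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'background.R'
    'enrichment.R'
    'io.R'
    'pipeline.R'
    'piwas-package.R'
    'piwas.R'
    'simulate.R'
    'stats.R'
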