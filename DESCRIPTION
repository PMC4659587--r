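Package: airrkit
Title: Post-Analysis of Immune Repertoire Clonotype Tables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for downstream analysis of processed adaptive immune
    receptor repertoire (AIRR) sequencing data. Reads tab-delimited clonotype
    tables, computes per-sample summary statistics, CDR3 spectratypes and
    V/J segment usage, estimates repertoire diversity (Chao1, Efron-Thisted,
    Shannon and Simpson effective numbers, multinomial rarefaction with
    extrapolation, downsampling-based normalization), quantifies pairwise
    repertoire overlap under configurable clonotype matching rules (including
    the batch-robust amino-acid-but-not-nucleotide rule), clusters samples by
    similarity or segment usage with permutation and Fisher exact group
    tests, tracks clonotypes across timepoints, and simulates seeded
    synthetic repertoire cohorts with planted group effects and
    public-clonotype sharing for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    ape
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'airrkit-package.R'
    'basic-stats.R'
    'cli.R'
    'cluster-stats.R'
    'diversity.R'
    'io.R'
    'overlap.R'
    'synthetic.R'
    'tracking.R'
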