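Package: CoupledOmics
Title: Coupled Metagenome-Metaproteome Community Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates taxon- and function-level count data from paired
    metagenomic (sequencing reads) and metaproteomic (peptide spectral
    matches) surveys of a microbial community. Implements protein-evidence
    filtering and NSAF quantification, technical-replicate averaging,
    library-normalized relative abundances and first-zeroed temporal deltas,
    read-versus-PSM concordance regression, per-taxon activity bias,
    cross-layer presence/absence classification, alpha-diversity indices,
    Bray-Curtis/NMDS/ANOSIM community comparison, a Laplace-smoothed GO-term
    differential test with per-taxon contribution breakdowns, and a
    seeded multinomial generator of coupled synthetic datasets with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    withr,
    S4Vectors,
    BiocGenerics,
    SummarizedExperiment,
    vegan
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'annotationMap.R'
    'anosim.R'
    'proteinSet.R'
    'countTable.R'
    'quant.R'
    'concordance.R'
    'diversity.R'
    'godiff.R'
    'io.R'
    'nmds.R'
    'simulate.R'
    'pipeline.R'
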