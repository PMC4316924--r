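Package: temenrich
Title: Tissue-Resident T Cell Transcriptomes and GWAS Locus Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline linking differential gene expression in
    tissue-resident effector-memory T cell subsets to genome-wide association
    study (GWAS) risk loci. Provides paired differential expression for
    small-n designed microarray experiments with detection-above-background
    filtering, expression-structure diagnostics (principal variance component
    analysis, top-variance hierarchical clustering, discriminant-ranked
    k-means), and a permutation-based enrichment test of differentially
    expressed genes within centiMorgan-defined windows around GWAS focal
    SNPs, with a locus-matched sampling null. A synthetic-data module
    generates fully self-describing inputs with known ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    Matrix,
    IRanges,
    GenomicRanges,
    S4Vectors,
    limma,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
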