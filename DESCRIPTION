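Package: trioma
Title: Integrative mRNA-lncRNA-miRNA Expression Analysis of Maturing and
    Ischemic Neurons
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for three-channel (mRNA, lncRNA, miRNA)
    microarray expression analysis of maturing primary neurons and neurons
    subjected to oxygen-glucose deprivation (OGD). Converts raw probe
    intensities to baseline-anchored Signal Log Ratios via quantile
    normalization, makes threshold-based differential-expression calls,
    classifies lncRNA loci by genomic orientation relative to coding genes
    (antisense/sense overlap, bidirectional, intergenic, with sub-region
    labels), computes Pearson trend correlations and t-test significance
    grades, classifies mRNA-lncRNA pairs as synergistic or inverse by
    cross-condition sign concordance, runs the gene-shortlisting cascade to
    an integrated lncRNA-mRNA-miRNA regulatory network, performs
    hypergeometric/EASE pathway enrichment, and supports 2^-ddCt qPCR
    quantification with presence calls and housekeeping-gene stability
    ranking. Includes a synthetic-data generator with planted ground truth
    so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
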