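Package: dsbskew
Title: Strand-Resolved Coverage and Resection Analysis at Induced DNA Double-Strand Breaks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing strand-preserving ChIP-seq and ATAC-seq data
    around site-specific DNA double-strand breaks (AsiSI, Cas9). Predicts
    nuclease and Cas9 cut coordinates on reference sequences, converts aligned
    paired-end fragments into filtered, strand-assigned, TMM-scaled binned
    coverage and strand-skew tracks, classifies fragments as spanning or
    ending at a cut, detects repair-junction deletions, compiles DSB-adjacent
    open-chromatin sites, builds site-by-sample signal matrices with Spearman
    correlations and fold-changes, and quantifies percent single-stranded DNA
    from restriction-protection qPCR Ct tables. Includes a synthetic
    paired-end fragment simulator with an explicit cut/resection/occupancy
    model so every stage can be exercised with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    Biostrings,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    GenomeInfoDb,
    Rsamtools,
    S4Vectors,
    edgeR,
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
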