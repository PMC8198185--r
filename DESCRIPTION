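Package: repairprime
Title: Strand-Resolved Excision Repair, Expression, and Chromatin
    Accessibility Integration for Cisplatin Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrative analysis of nucleotide excision repair,
    transcription, and chromatin accessibility in paired
    cisplatin-sensitive/resistant cell lines. Provides strand-aware
    genomic interval algebra on BED-convention coordinates,
    strand-resolved quantification of excision-repair (XR-seq) reads
    with a transcription-coupled versus global-genome repair bias
    statistic, TSS and peak-anchored binned metaprofiles, an in-package
    negative-binomial differential-expression chain (median-of-ratios
    size factors, moment-based shrunk dispersions, Wald tests),
    reproducible ATAC-seq peak merging across replicates, and the
    "primed gene" intersection caller that flags genes upregulated by
    treatment in the sensitive line and constitutively elevated in the
    resistant line. A synthetic-data module generates genomes, repair
    reads, RNA-seq counts, and replicate peak sets with the statistical
    structure the analysis assumes, together with ground truth for
    recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
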