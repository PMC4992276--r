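Package: crzKinetics
Title: Time-Resolved ChIP-Seq Analysis of Crz1 Promoter Recruitment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for time-course ChIP-Seq analysis of transcription factor
    recruitment to intergenic regions, modelled on the rapid recruitment of the
    calcineurin-regulated factor Crz1 to yeast promoters under alkaline-pH
    stress. Provides 50-nt bin quantitation with duplicate removal and
    depth normalization, fold-enrichment peak calling with a kinetic filter,
    strength classification, CDRE motif scanning with exact p-value score
    thresholds, position weight matrix refinement and consensus derivation,
    TSS-aligned percent-of-fold-change binding profiles, chromatin
    accessibility association statistics, and a synthetic-data generator that
    plants peaks of known strength and kinetic class for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    BiocGenerics,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
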