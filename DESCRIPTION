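Package: ChIPdirect
Title: Direct Transcription-Factor Target Identification from Replicated
    ChIP-Seq and Genotype-Contrast RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies direct, condition-dependent transcription-factor
    target genes by integrating replicated ChIP-seq peak sets with
    genotype-contrast differential-expression results. Implements
    reciprocal-overlap consensus peak construction across replicates
    (80 percent of the shortest segment), cross-condition peak matching via
    peak-center windows (+/- 30 percent of segment length), promoter /
    start-overlap / gene-body peak-to-gene annotation, combination of
    binding evidence with expression classes into candidate sets for direct
    activation and repression, hypergeometric gene-set overlap tests,
    degenerate (IUPAC) motif scanning with peak-center and
    length-normalized gene-body positional statistics, and a fully
    reproducible synthetic-data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    BiocGenerics,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
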