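Package: nanomod
Title: Error-Profile RNA Modification Calling for Nanopore Long-Read
    Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing nanopore native-RNA and direct-cDNA
    transcriptome sequencing runs and for inferring RNA modifications from
    systematic base-calling errors. Provides read-level quality control and
    CIGAR-based classification (mapped, unmapped, chimeric, other), per-base
    error pileups, one-sided exact testing of the error at specific base (ESB)
    against a background error model, replicate-aware differential
    modification testing via the Cochran-Mantel-Haenszel procedure,
    transcript-level count tables, sites-per-transcript and Jaccard
    commonality summaries, and a synthetic nanopore-read simulator that
    reproduces background errors, error-elevating modified sites, 3'
    coverage bias, chimeric reads, strand bias and pass/fail read qualities
    for validation at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
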