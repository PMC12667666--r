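Package: m7Gtrac
Title: TRAC-Seq tRNA m7G Site Calling and Translation Efficiency Analysis
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for chemical-cleavage tRNA sequencing (TRAC-seq) analysis of
    N7-methylguanosine (m7G) modifications. Provides a synthetic-data generator
    for cleavage libraries and ribosome-association (RNC-seq) / RNA-seq count
    matrices, ungapped read alignment to mature tRNA references with SAM import,
    5'-end pileup tracks and reverse-transcription-stop fractions, binomial
    m7G site calling with replicate merging and cross-condition comparison,
    position-frequency-matrix motif consensus around called sites, moderated
    differential translation-efficiency testing, anticodon-codon decoding maps
    with per-gene decoded-codon usage, a 2^(-DeltaDeltaCt) qPCR screen, and a
    reproducible end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
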