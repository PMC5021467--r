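Package: pyroscreen
Title: Amplicon Pyrosequencing Screening with Flowgram-Based Homopolymer Review
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for diagnostic amplicon resequencing on
    454-style pyrosequencing data. Reads and writes Standard Flowgram Format
    (SFF) files, demultiplexes reads by MID barcode, aligns them to amplicon
    references, builds strand-aware pileups and calls candidate variants, and
    validates calls with depth, frequency, strand and read-support rules.
    Candidate indels in homopolymer tracts are reviewed through dual-resolution
    histograms of the raw flowgram signals, optionally classified by a
    Gaussian-mixture model into wild type, heterozygous or homozygous indel, or
    quantitation artefact. Validated variants are annotated in HGVS coding
    nomenclature from a GenBank gene model, matched against a user-supplied
    neutral-variant list, and written to coverage, variant and resequencing
    reports. A seeded pyrosequencing simulator with a homopolymer noise model
    generates SFF input and ground truth so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr,
    yaml
Config/testthat/edition: 3
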