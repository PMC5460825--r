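Package: grchip
Title: Glucocorticoid Receptor ChIP-Seq Peak Calling and Motif Architecture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for analysing glucocorticoid receptor (GR)
    chromatin immunoprecipitation sequencing data in brain tissue: tag
    extension, deduplication and depth normalisation; hotspot-style
    replicate-concordant peak calling against matched input; negative-binomial
    differential binding between conditions; nearest-TSS annotation with a
    -5 kb/+100 bp promoter definition; and consensus-motif architecture
    analysis of binding sites (palindromic GRE, GRE half-site, NF-1 half-site,
    bHLH/E-box and variable-spacer negative GRE), including positional
    histograms, strength stratification and composite-motif classes. Ships a
    synthetic-data generator that plants binding sites with configurable motif
    composition on a motif-free background genome so the whole pipeline is
    testable against planted ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
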