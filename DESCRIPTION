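Package: bdrive
Title: Analysis of Supernumerary B Chromosome Drive
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct how a supernumerary (B) chromosome and its
    drive-control region are identified from sequencing data: coverage-based
    assignment of assembly contigs to the B chromosome via a two-component
    mixture model, ordering of B contigs into a pseudomolecule using satellite
    repeats as positional landmarks, deletion mapping of the drive control
    region (DCR) from comparative read-depth tracks of drive-positive and
    drive-negative karyotype variants, a tile/read ratio estimator of
    satellite-repeat assembly completeness, a staged subtractive
    negative-binomial differential-expression funnel with sequence clustering
    and in-silico PCR exclusivity filtering, and pollen-FISH drive-frequency
    statistics with Wilson confidence intervals. A synthetic-data module
    generates toy genomes, karyotype variants, coverage tracks, reads, RNA-seq
    count matrices and pollen count tables with known ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    Biostrings,
    IRanges,
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
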