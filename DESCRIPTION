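Package: SSRpanel
Title: Transcriptome Microsatellite Mining and Marker Panel Characterization
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for developing microsatellite (SSR) marker panels from
    assembled transcriptomes and characterizing them in population samples.
    Detects perfect tandem repeats (motif lengths 2-10) in transcript
    sequences, selects potentially amplifiable loci (PAL) with sufficient
    flanking sequence for primer design, reads and writes Genepop genotype
    files, bins raw fragment sizes into integer alleles, and computes
    per-locus population-genetic statistics: observed and unbiased expected
    heterozygosity, the exact Hardy-Weinberg probability test on the
    conditional distribution of genotype tables, maximum-likelihood
    null-allele frequency estimation by EM, permutation G-tests of genotypic
    disequilibrium, and Bonferroni correction. Panel-level reports summarize
    polymorphism and cross-species transferability. A synthetic-data module
    generates transcriptomes with planted SSRs and genotype matrices with
    controlled Hardy-Weinberg departures and null alleles, with full ground
    truth, so the whole workflow is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
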