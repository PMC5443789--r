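Package: crisprquant
Title: Quantification of CRISPR Editing Outcomes from Amplicon Deep Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying CRISPR/Cas9 and paired-nickase genome
    editing from amplicon deep-sequencing reads: Phred-quality read
    truncation, semi-global affine-gap alignment of reads to amplicon
    references with indel extraction and left-normalization, editing-rate
    estimation in a window around the predicted cleavage site with a
    displaced background control window and a paired t-test, in-silico
    restriction digests (RFLP) and clone genotyping, paired-guide
    genomic-deletion PCR genotyping, and log-linear fitting of episomal
    vector loss per cell generation.  A synthetic-data module generates
    amplicons, edited alleles, FASTQ reads and qPCR-style decay series so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    S4Vectors,
    stats,
    tibble,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
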