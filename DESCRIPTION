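Package: duplexrepair
Title: Strand-Resolved Duplex Sequencing Analysis of Double-Strand Break Repair
Version: 0.1.0
Authors@R:
    person("duplexrepair", "maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for single-molecule, strand-resolved analysis of
    nonhomologous end-joining (NHEJ) repair products on designed
    extrachromosomal double-strand break substrates. A double-stranded
    sequencing adapter carrying a 10-nt unique molecular identifier (UMI)
    links the two strands of each repaired duplex; a 5-nt mismatched
    strand-ID region identifies which physical strand a read derives from.
    The package enumerates the reference junction sequences expected for
    every repair path (direct ligation, templated +C/+TC/+CTC insertions,
    and semi-conservative copies of the opposite strand), annotates reads
    by sample barcode, UMI, strand and junction, reconstructs duplex
    molecules per UMI with oversampling-ratio and minor-strand filters,
    and classifies each molecule as repaired by a parallel/symmetric path
    (model 1) or an ordered/semi-conservative path (model 2). A simulator
    of two-strand exponential repair kinetics and UMI-tagged, error-bearing
    amplicon reads exercises every stage without external data, and helper
    functions implement spike-in normalized qPCR fold changes, droplet
    digital PCR Poisson concentrations, and the alkali-sensitivity
    fraction-RNA estimate for embedded ribonucleotides.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
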