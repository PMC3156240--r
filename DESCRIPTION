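Package: mirseek
Title: Small RNA Sequencing Analysis and MicroRNA Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end small RNA sequencing toolkit for two-library
    comparative microRNA studies in species without a sequenced genome.
    Cleans and collapses raw reads, maps tags to a surrogate reference
    genome with a one-mismatch tolerance, triages other non-coding RNA and
    repeat-associated small RNAs, profiles conserved microRNAs against a
    mature reference set, and discovers novel microRNAs by two routes: a
    genome-anchored search that excises and folds candidate precursor
    hairpins, and a genome-free search that pairs unmapped tags into
    miRNA/miRNA* duplexes joined by a hairpin-forming linker. Includes a
    nearest-neighbour minimum-free-energy folding engine, TPM
    normalisation with log2 fold-class profiling, and a synthetic-data
    generator that plants ground-truth loci for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    ape,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
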