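Package: spuriometer
Title: Quantify and Reduce Spurious Alignments of Ultra-Short Ancient DNA
    Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements an artificial-mutation approach to measuring how many
    ultra-short (20-45 bp) ancient DNA sequences align to a reference genome
    purely by chance. A reference genome is mutated at conserved, regularly
    spaced sites while preserving its nucleotide composition; alignments
    overlapping the mutated sites are classified as true or spurious, with a
    strand-orientation guard against cytosine-deamination artefacts;
    misclassification-corrected spurious-alignment fractions are estimated per
    sequence length, yielding sample-specific length cutoffs (L1%, L10%) and
    the effect of deamination and indel filters. Also provides length-dependent
    unique-mappability tracks for small genomes, a derived-allele-sharing
    lineage-assignment test for archaic hominins, and a synthetic-data
    generator for endogenous (deaminated, short-fragment) and contaminant
    reads with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    GenomicAlignments,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    Rsamtools,
    rtracklayer,
    optparse
Config/testthat/edition: 3
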