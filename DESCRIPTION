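Package: snpclassify
Title: Offline Functional Classification of SNPs, MNPs, Inversions and Indels
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Annotates sequence variants (SNPs, multi-nucleotide
    polymorphisms, inversions and indels) against transcript models loaded
    from GFF3 or BED12, entirely offline.  Each variant is checked against
    the reference genome, typed from its alleles, matched against an
    optional known-variants VCF (KNOWN/NOVEL/ALTERNATIVE status), and
    assigned one or more of 21 functional classes per transcript, including
    codon-level consequences under a selectable genetic code, splice-window
    classes, start/stop gain and loss, and complex-deletion subclasses.
    Indels are left-normalized so that equivalently placed records in
    repeat regions are recognized as one and the same event; repeat period
    length, duplication/inversion/shift genesis flags and a transposon
    flank check characterize them further.  A deterministic synthetic
    fixture generator produces genomes, annotations and truth-labelled
    variant lists covering every class.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
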