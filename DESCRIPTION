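Package: mhcloci
Title: Minimum Locus-Number Inference for MHC Class II B Genes from
    Cloned Allele Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the minimum number of loci of a polymorphic
    multigene family (MHC class II B in flatfishes as the motivating
    system) in diploid individuals from cloned allele sequences.
    Implements clone-support allele validation, spliced alignment of
    cDNA onto genomic alleles with canonical GT-AG intron boundaries,
    polymorphic-site counting, Nei-Gojobori (1986) codon-based tests of
    positive selection with a codon-bootstrap Z statistic,
    diploid-constrained agglomerative grouping of alleles into candidate
    loci, intron tandem-repeat (microsatellite) profiling, and a
    ground-truthed simulator of multi-locus diploid cloning data used to
    validate every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    jsonlite,
    rlang,
    rtracklayer,
    stats,
    utils
Suggests:
    BiocGenerics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
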