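#!/usr/bin/env Rscript
# Clone-support allele validation: collapse the clone sequences from 01
# into validated alleles (>= 3 identical clones within one individual),
# build the genotype table, and report what was discarded.

library(mhcloci)

records <- read_fasta("results/sim/clones.fasta")
meta <- read_clone_metadata("results/sim/clones.tsv")
seqs <- seq_strings(records)
clones <- data.frame(clone_id = meta$clone_id, individual_id = meta$individual_id,
                     source = meta$source, residues = unname(seqs[meta$clone_id]))

aset <- collapse_clones(clones, min_support = 3L, prefix = "Sim-DAB")
files <- write_allele_set(aset, "results/validation")

counts <- allele_counts(aset$genotypes[aset$genotypes$source == "gdna", ])
message(sprintf("validated %d alleles (%d cDNA, %d gDNA); discarded %d sequences",
                nrow(aset$alleles), sum(aset$alleles$source == "cdna"),
                sum(aset$alleles$source == "gdna"), nrow(aset$discards)))
message(sprintf("genomic alleles per individual: %s (diploid bound %d)",
                paste(sprintf("%s=%d", names(counts), counts), collapse = " "),
                min_locus_bound(counts)))
message("wrote: ", paste(files, collapse = ", "))
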