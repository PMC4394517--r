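#!/usr/bin/env Rscript
# Polymorphism and selection: align the validated cDNA alleles, count
# polymorphic sites per region, classify substitutions against the most
# supported allele, and run the NG86 codon Z-test in the peptide-binding
# region (exons 2-3) versus the rest of the ORF.

library(mhcloci)

alleles <- read_fasta("results/validation/alleles.fasta")
src <- vapply(alleles, function(r) sub(".*source=([a-z]+).*", "\\1", r$description), "")
cdna <- alleles[src == "cdna"]
seqs <- seq_strings(cdna)

msa <- build_msa(seqs)
orf <- find_orf(cdna[[1]])

# exon map from the first annotated genomic allele
ann <- list.files("results/annotation", pattern = "\\.json$", full.names = TRUE)
model_doc <- jsonlite::fromJSON(ann[[1]])
exon_model <- structure(list(
  genomic_id = model_doc$genomic_id, cdna_id = model_doc$cdna_id,
  exons = cbind(start = model_doc$exons$start, end = model_doc$exons$end),
  introns = cbind(start = model_doc$introns$start, end = model_doc$introns$end),
  cdna_len = model_doc$cdna_len, utr5_len = model_doc$utr5_len,
  utr3_len = model_doc$utr3_len,
  orf = structure(list(found = TRUE, start = model_doc$orf$start,
                       end = model_doc$orf$end, protein = model_doc$orf$protein),
                  class = "orf_annotation"),
  mismatches = model_doc$mismatches
), class = "gene_model")
regions <- partition_regions(exon_model, "pbr_vs_rest")

dir.create("results/selection", showWarnings = FALSE, recursive = TRUE)
poly <- polymorphic_sites(msa, regions)
message(sprintf("%d polymorphic sites among %d cDNA alleles (PBR %d, non-PBR %d)",
                poly$total, length(seqs), poly$per_region[["PBR"]],
                poly$per_region[["nonPBR"]]))

subs <- do.call(rbind, lapply(seq_along(seqs)[-1], function(j) {
  s <- classify_substitutions(seqs[[1]], seqs[[j]], orf)
  if (nrow(s)) cbind(allele = names(seqs)[[j]], s) else NULL
}))
write.table(subs, "results/selection/substitutions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cod <- codon_alignment(msa, orf)
rows <- lapply(names(regions$codons), function(rn) {
  st <- selection_test(cod, regions$codons[[rn]], n_bootstrap = 1000L, seed = 42L,
                       region_name = rn)
  print(st)
  data.frame(region = rn, n_codons = st$n_codons, dN = st$dN, dS = st$dS,
             ratio = st$ratio, Z = st$Z, p = st$p)
})
write.table(do.call(rbind, rows), "results/selection/selection.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_msa_fasta(msa, "results/selection/cdna_alleles.aln.fasta")
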