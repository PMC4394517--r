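#!/usr/bin/env Rscript
# Exon/intron annotation: spliced-align each validated genomic allele
# against its cDNA counterpart (GT..AG introns, exact splice), export the
# gene models as GFF3 + JSON, and record the spliced exon sequences that
# the locus inference (05) will compare.

library(mhcloci)

alleles <- read_fasta("results/validation/alleles.fasta")
src <- vapply(alleles, function(r) sub(".*source=([a-z]+).*", "\\1", r$description), "")
cdna <- alleles[src == "cdna"]
gdna <- alleles[src == "gdna"]

dir.create("results/annotation", showWarnings = FALSE, recursive = TRUE)
models <- list()
exon_rows <- list()
for (g in gdna) {
  pre <- substr(g$residues, 1, 40)
  order_c <- order(vapply(cdna, function(cd) substr(cd$residues, 1, 40) != pre, logical(1)))
  for (cd in cdna[order_c]) {
    m <- tryCatch(spliced_align(cd, g), unannotatable_error = function(e) NULL)
    if (!is.null(m)) { models[[g$seq_id]] <- m; break }
  }
  if (is.null(models[[g$seq_id]])) {
    message(g$seq_id, ": no cDNA splices onto this allele; skipped")
    next
  }
  m <- models[[g$seq_id]]
  export_gff3(m, file.path("results/annotation", paste0(g$seq_id, ".gff3")))
  export_gene_model_json(m, file.path("results/annotation", paste0(g$seq_id, ".json")))
  ex <- m$exons
  exon_rows[[g$seq_id]] <- data.frame(
    allele = g$seq_id, n_exons = nrow(ex), n_introns = nrow(m$introns),
    exon_seq = paste(substring(g$residues, ex[, "start"] + 1, ex[, "end"]), collapse = ""),
    intron_lengths = paste(m$introns[, "end"] - m$introns[, "start"], collapse = ",")
  )
}
tab <- do.call(rbind, exon_rows)
write.table(tab, "results/annotation/exon_table.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("annotated %d/%d genomic alleles; exon counts: %s",
                nrow(tab), length(gdna),
                paste(sort(unique(tab$n_exons)), collapse = ",")))
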