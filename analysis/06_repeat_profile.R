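#!/usr/bin/env Rscript
# Intron microsatellite profiling: tabulate per-allele intron lengths with
# their dominant tandem repeat, grouped by inferred locus -- the signal
# that makes intron length a locus-diagnostic marker.

library(mhcloci)

alleles <- read_fasta("results/validation/alleles.fasta")
gseqs <- seq_strings(alleles)
ann <- list.files("results/annotation", pattern = "\\.json$", full.names = TRUE)
models <- list()
for (f in ann) {
  doc <- jsonlite::fromJSON(f)
  models[[doc$genomic_id]] <- structure(list(
    genomic_id = doc$genomic_id, cdna_id = doc$cdna_id,
    exons = cbind(start = doc$exons$start, end = doc$exons$end),
    introns = cbind(start = doc$introns$start, end = doc$introns$end),
    cdna_len = doc$cdna_len, utr5_len = doc$utr5_len, utr3_len = doc$utr3_len,
    orf = structure(list(found = TRUE, start = doc$orf$start, end = doc$orf$end,
                         protein = doc$orf$protein), class = "orf_annotation"),
    mismatches = doc$mismatches
  ), class = "gene_model")
}
grouping_doc <- jsonlite::fromJSON("results/loci/grouping.json", simplifyVector = FALSE)
grouping <- structure(list(
  groups = lapply(grouping_doc$groups, unlist),
  unassigned = unlist(grouping_doc$unassigned)
), class = "locus_grouping")

tab <- intron_length_table(models, as.list(gseqs[names(models)]), grouping = grouping)
dir.create("results/repeats", showWarnings = FALSE, recursive = TRUE)
write.table(tab, "results/repeats/intron_table.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

by_group <- aggregate(length ~ group + intron, tab,
                      function(x) paste(sort(unique(x)), collapse = "/"))
message("intron lengths by inferred locus group:")
for (i in sort(unique(by_group$intron))) {
  sub <- by_group[by_group$intron == i, ]
  message(sprintf("  intron %d: %s", i,
                  paste(sprintf("%s=%s", sub$group, sub$length), collapse = "  ")))
}
units <- sort(table(tab$dominant_unit[tab$dominant_unit != "none"]), decreasing = TRUE)
message("dominant repeat units: ",
        paste(sprintf("%s x%d", names(units), units), collapse = ", "))
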