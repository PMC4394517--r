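#!/usr/bin/env Rscript
# Analyses of the deposited flatfish sequences. Runs only when the GenBank
# downloads are present under inst/extdata/genbank/ (see the README there);
# each block reports the statistic it recomputes.

library(mhcloci)

gb <- function(name) {
  local <- file.path("inst/extdata/genbank", name)
  if (file.exists(local)) return(local)
  installed <- system.file("extdata", "genbank", name, package = "mhcloci")
  if (nzchar(installed) && file.exists(installed)) return(installed)
  NA_character_
}
have <- function(...) all(!is.na(vapply(list(...), gb, character(1))))
dir.create("results/reference", showWarnings = FALSE, recursive = TRUE)

orf_seqs_of <- function(recs) {
  out <- vapply(recs, function(r) {
    o <- find_orf(r)
    substr(r$residues, o$start + 1, o$end)
  }, character(1))
  setNames(out, vapply(recs, `[[`, character(1), "seq_id"))
}

if (have("stone_flounder_cdna.fasta")) {
  recs <- read_fasta(gb("stone_flounder_cdna.fasta"))
  msa <- build_msa(orf_seqs_of(recs))
  poly <- polymorphic_sites(msa)
  message(sprintf("stone flounder: %d polymorphic sites among %d cDNA ORFs",
                  poly$total, length(recs)))
  write_msa_fasta(msa, "results/reference/stone_flounder_orfs.aln.fasta")
} else {
  message("stone_flounder_cdna.fasta not present; skipping cDNA polymorphism")
}

if (have("stone_flounder_cdna.fasta", "japanese_flounder_cdna.fasta",
         "japanese_flounder_gdna.fasta")) {
  recs <- read_fasta(gb("stone_flounder_cdna.fasta"))
  seqs <- orf_seqs_of(recs)
  msa <- build_msa(seqs)
  jf_c <- read_fasta(gb("japanese_flounder_cdna.fasta"))[[1]]
  jf_g <- read_fasta(gb("japanese_flounder_gdna.fasta"))[[1]]
  model <- spliced_align(jf_c, jf_g)
  message(sprintf("Japanese flounder gene: %d exons, %d introns, %d bp genomic",
                  nrow(model$exons), nrow(model$introns), nchar(jf_g$residues)))
  regions <- partition_regions(model, "pbr_vs_rest")
  cod <- codon_alignment(msa, find_orf(seqs[[1]]))
  rows <- lapply(names(regions$codons), function(rn) {
    st <- selection_test(cod, regions$codons[[rn]], n_bootstrap = 1000L, seed = 1L,
                         region_name = rn)
    print(st)
    data.frame(region = rn, dN = st$dN, dS = st$dS, ratio = st$ratio, Z = st$Z, p = st$p)
  })
  write.table(do.call(rbind, rows), "results/reference/selection.tsv",
              sep = "\t", quote = FALSE, row.names = FALSE)

  jf_all <- read_fasta(gb("japanese_flounder_cdna.fasta"))
  jf_msa <- build_msa(seq_strings(jf_all))
  message(sprintf("Japanese flounder: %d polymorphic sites among %d cDNA alleles",
                  polymorphic_sites(jf_msa)$total, length(jf_all)))
  jf_orf <- find_orf(jf_all[[1]])
  subs <- do.call(rbind, lapply(seq_along(jf_all)[-1], function(j) {
    s <- classify_substitutions(jf_all[[1]], jf_all[[j]], jf_orf)
    if (nrow(s)) cbind(allele = jf_all[[j]]$seq_id, s) else NULL
  }))
  if (!is.null(subs)) {
    write.table(subs, "results/reference/jf_substitutions.tsv", sep = "\t",
                quote = FALSE, row.names = FALSE)
    message("substitutions vs the most common allele: ",
            paste(ifelse(subs$kind == "synonymous", subs$cdna_notation,
                         subs$protein_notation), collapse = ", "))
  }
} else {
  message("Japanese flounder pair not present; skipping structure/selection")
}

if (have("stone_flounder_wholelength.fasta", "stone_flounder_cdna.fasta")) {
  gds <- read_fasta(gb("stone_flounder_wholelength.fasta"))
  cds <- read_fasta(gb("stone_flounder_cdna.fasta"))
  models <- list()
  gseqs <- list()
  for (g in gds) {
    for (cd in cds) {
      m <- tryCatch(spliced_align(cd, g, max_mismatch_per_exon = 5L),
                    unannotatable_error = function(e) NULL)
      if (!is.null(m)) { models[[g$seq_id]] <- m; gseqs[[g$seq_id]] <- g$residues; break }
    }
  }
  if (length(models)) {
    tab <- intron_length_table(models, gseqs)
    write.table(tab, "results/reference/intron_table.tsv", sep = "\t",
                quote = FALSE, row.names = FALSE)
    message(sprintf("annotated %d/%d whole-length alleles; intron 3 lengths: %s",
                    length(models), length(gds),
                    paste(tab$length[tab$intron == 3], collapse = ", ")))
  }
} else {
  message("whole-length alleles not present; skipping intron profiling")
}
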