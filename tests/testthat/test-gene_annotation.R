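test_that("an intronless gene aligns to a single exon spanning the cDNA", {
  s <- seq_record("x", "ATGGCCAAATTTGGGCCCAAATTTGGGCCCTAA")
  m <- spliced_align(s, seq_record("g", s$residues), min_exon = 5)
  expect_equal(nrow(m$exons), 1L)
  expect_equal(unname(m$exons[1, ]), c(0L, nchar(s$residues)))
  expect_equal(nrow(m$introns), 0L)
  expect_equal(nrow(extract_introns(m, s)), 0L)
})

test_that("simulated alleles re-annotate to their exact truth exon coordinates", {
  for (seed in 1:10) {
    sim <- simulate_dataset(small_sim_config(seed))
    al <- sim$truth$loci[[1]]$alleles[[1]]
    m <- spliced_align(seq_record("c", al$cdna), seq_record("g", al$gdna), min_exon = 15)
    expect_identical(unname(m$exons[, "start"]), unname(as.integer(al$exons[, "start"])))
    expect_identical(unname(m$exons[, "end"]), unname(as.integer(al$exons[, "end"])))
    expect_equal(m$mismatches, 0L)
    # splicing round trip: exon concatenation reproduces the cDNA
    spliced <- paste(substring(al$gdna, m$exons[, "start"] + 1, m$exons[, "end"]), collapse = "")
    expect_identical(spliced, al$cdna)
    expect_equal(nrow(m$introns), nrow(m$exons) - 1L)
    # introns are canonical and lengths match the interval widths
    intr <- extract_introns(m, seq_record("g", al$gdna))
    expect_true(all(startsWith(intr$residues, "GT")))
    expect_true(all(endsWith(intr$residues, "AG")))
    expect_equal(intr$length, nchar(intr$residues))
  }
})

test_that("genomic flanks around the gene do not disturb the annotation", {
  sim <- simulate_dataset(small_sim_config(3))
  al <- sim$truth$loci[[2]]$alleles[[1]]
  flank5 <- "CCCCCTTTTTCCCCC"
  g2 <- seq_record("g", paste0(flank5, al$gdna, "GGGGGAAAAA"))
  m <- spliced_align(seq_record("c", al$cdna), g2, min_exon = 15)
  expect_identical(unname(m$exons[, "start"]),
                   unname(as.integer(al$exons[, "start"])) + nchar(flank5))
})

test_that("an unannotatable pair raises a typed error carrying the partial chain", {
  set.seed(21)
  cdna <- seq_record("c", random_dna(120))
  gdna <- seq_record("g", random_dna(400))
  err <- tryCatch(spliced_align(cdna, gdna), unannotatable_error = function(e) e)
  expect_s3_class(err, "unannotatable_error")
  expect_true(is.list(err$partial))
})

test_that("region partitions cover the ORF and split out exons 2-3 as the PBR", {
  sim <- simulate_dataset(small_sim_config(5))
  al <- sim$truth$loci[[1]]$alleles[[2]]
  m <- spliced_align(seq_record("c", al$cdna), seq_record("g", al$gdna), min_exon = 15)

  per_exon <- partition_regions(m, "per_exon")
  iv <- do.call(rbind, per_exon$intervals)
  expect_equal(unname(iv[1, 1]), 0)
  expect_equal(unname(iv[nrow(iv), 2]), m$cdna_len)
  expect_true(all(iv[-1, 1] == iv[-nrow(iv), 2]))  # contiguous cover

  pbr <- partition_regions(m, "pbr_vs_rest")
  n_sense <- (m$orf$end - m$orf$start) %/% 3 - 1
  expect_setequal(c(pbr$codons$PBR, pbr$codons$nonPBR), seq_len(n_sense))
  expect_length(intersect(pbr$codons$PBR, pbr$codons$nonPBR), 0)
  # PBR interval is codon-aligned within the ORF
  expect_equal(unname((pbr$intervals$PBR[1, "start"] - m$orf$start) %% 3), 0)
  expect_equal(unname((pbr$intervals$PBR[1, "end"] - m$orf$start) %% 3), 0)
  # PBR + nonPBR interval widths add up to the ORF length
  w <- function(mat) sum(mat[, "end"] - mat[, "start"])
  expect_equal(w(pbr$intervals$PBR) + w(pbr$intervals$nonPBR), m$orf$end - m$orf$start)

  two_exon <- spliced_align(seq_record("c2", "ATGAAACCCGGGTTTACATGCTGA"),
                            seq_record("g2", paste0("ATGAAACCCGGG", "GTAAAACCCCAG", "TTTACATGCTGA")),
                            min_exon = 10)
  expect_equal(nrow(two_exon$exons), 2L)
  expect_error(partition_regions(two_exon, "pbr_vs_rest"), "at least 3 exons")
})

test_that("gene models export to GFF3 and JSON faithfully", {
  sim <- simulate_dataset(small_sim_config(8))
  al <- sim$truth$loci[[1]]$alleles[[1]]
  m <- spliced_align(seq_record("c", al$cdna), seq_record("g", al$gdna), min_exon = 15)

  gff <- withr::local_tempfile(fileext = ".gff3")
  export_gff3(m, gff)
  back <- rtracklayer::import(gff)
  exon_feats <- back[back$type == "exon"]
  expect_equal(length(exon_feats), nrow(m$exons))
  expect_equal(BiocGenerics::start(exon_feats), unname(m$exons[, "start"]) + 1)
  expect_equal(BiocGenerics::end(exon_feats), unname(m$exons[, "end"]))

  js <- jsonlite::fromJSON(export_gene_model_json(m), simplifyVector = TRUE)
  expect_equal(js$cdna_len, m$cdna_len)
  expect_equal(js$exons$start, unname(m$exons[, "start"]))
  expect_equal(nchar(js$orf$protein), (m$orf$end - m$orf$start) / 3 - 1)
})

test_that("cDNA intervals map back through the model onto genomic exon pieces", {
  sim <- simulate_dataset(small_sim_config(13))
  al <- sim$truth$loci[[1]]$alleles[[1]]
  m <- spliced_align(seq_record("c", al$cdna), seq_record("g", al$gdna), min_exon = 15)
  piece <- map_cdna_to_genomic(m, c(m$orf$start, m$orf$end))
  got <- paste(substring(al$gdna, piece[, "start"] + 1, piece[, "end"]), collapse = "")
  expect_identical(got, substr(al$cdna, m$orf$start + 1, m$orf$end))
})
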