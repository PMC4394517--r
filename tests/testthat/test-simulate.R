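test_that("invalid configurations are rejected with the offending fields listed", {
  expect_error(sim_config(n_loci = 0), "n_loci")
  expect_error(sim_config(error_rate = 2), "error_rate")
  expect_error(sim_config(utr5_len = 100, exon_lengths = c(79L, 270L, 282L, 90L, 33L, 40L)),
               "5'UTR")
  expect_error(sim_config(exon_lengths = c(80L, 270L, 282L, 90L, 33L, 40L)),
               "divisible by 3")
  expect_error(sim_config(clone_depth = c(5L, 2L)), "clone_depth")
})

test_that("two runs with the same configuration are byte-identical", {
  a <- simulate_dataset(small_sim_config(23))
  b <- simulate_dataset(small_sim_config(23))
  expect_identical(a$clones, b$clones)
  expect_identical(a$run_id, b$run_id)
  expect_identical(jsonlite::toJSON(a$truth, auto_unbox = TRUE, digits = NA),
                   jsonlite::toJSON(b$truth, auto_unbox = TRUE, digits = NA))
  c_ <- simulate_dataset(small_sim_config(24))
  expect_false(identical(a$run_id, c_$run_id))
})

test_that("the generator honours its own structural contracts", {
  sim <- simulate_dataset(small_sim_config(29))
  cfg <- sim$truth$config
  for (l in sim$truth$loci) {
    for (a in l$alleles) {
      # every cDNA carries a complete stop-free ORF of the configured length
      orf <- find_orf(a$cdna)
      expect_true(orf$found)
      expect_equal(orf$end - orf$start,
                   sum(cfg$exon_lengths) - cfg$utr5_len - cfg$utr3_len)
      # splicing truth exons out of the genomic allele gives back the cDNA
      spliced <- paste(substring(a$gdna, a$exons[, "start"] + 1, a$exons[, "end"]),
                       collapse = "")
      expect_identical(spliced, a$cdna)
    }
  }
  # diploid constraint in the truth genotypes
  per <- stats::aggregate(allele ~ individual_id + locus, sim$truth$genotypes,
                          function(x) length(unique(x)))
  expect_true(all(per$allele <= 2))
})

test_that("noiseless deep cloning recovers the truth exactly for any seed", {
  for (seed in c(31, 37)) {
    sim <- simulate_dataset(small_sim_config(seed, error_rate = 0, clone_depth = c(3L, 4L)))
    aset <- collapse_clones(sim$clones, min_support = 3)
    got <- sort(unique(aset$alleles$residues[aset$alleles$source == "cdna"]))
    want <- sort(unique(unname(sim_carried_alleles(sim, "cdna"))))
    expect_identical(got, want)
  }
})

test_that("PBR-targeted mutation pressure raises dN in the PBR relative to the rest", {
  diffs <- numeric(0)
  for (seed in 1:8) {
    sim <- simulate_dataset(small_sim_config(seed, pbr_multiplier = 8,
                                             allele_divergence = 0.02))
    pool <- sim_carried_alleles(sim, "cdna")
    pool <- pool[!duplicated(pool)]
    if (length(pool) < 3) next
    orf <- find_orf(pool[[1]])
    cod <- codon_alignment(build_msa(pool), orf)
    al <- sim$truth$loci[[1]]$alleles[[1]]
    m <- spliced_align(seq_record("c", al$cdna), seq_record("g", al$gdna), min_exon = 15)
    reg <- partition_regions(m, "pbr_vs_rest")
    pbr <- selection_test(cod, reg$codons$PBR, n_bootstrap = 50, seed = seed)
    non <- selection_test(cod, reg$codons$nonPBR, n_bootstrap = 50, seed = seed)
    diffs <- c(diffs, (pbr$dN - pbr$dS) - (non$dN - non$dS))
  }
  expect_gt(mean(diffs > 0), 0.5)
})

test_that("truth scorecards quantify recovery and degrade monotonically with error", {
  sim <- simulate_dataset(small_sim_config(41, error_rate = 0))
  truth_seqs <- unique(c(sim_carried_alleles(sim, "cdna"), sim_carried_alleles(sim, "gdna")))
  ideal <- truth_compare(list(alleles = truth_seqs, min_locus_estimate = 2L,
                              run_id = sim$run_id),
                         sim$truth)
  expect_equal(ideal$allele_recovery, 1.0)
  expect_equal(ideal$locus_count_error, 0L)

  n <- length(unique(truth_seqs))
  dropped <- truth_compare(list(alleles = truth_seqs[-1]), sim$truth)
  expect_equal(dropped$allele_recovery, 1 - 1 / n)

  expect_error(truth_compare(list(alleles = truth_seqs, run_id = "bogus"), sim$truth),
               "different runs")

  # recovery is non-increasing as the clone error rate grows
  rates <- c(0, 0.005, 0.02, 0.08)
  rec <- vapply(rates, function(r) {
    s <- simulate_dataset(small_sim_config(43, error_rate = r))
    aset <- suppressWarnings(collapse_clones(s$clones, min_support = 3))
    sc <- truth_compare(list(alleles = aset$alleles$residues), s$truth)
    sc$allele_recovery
  }, numeric(1))
  expect_true(all(diff(rec) <= 0))
})

test_that("written datasets round-trip through the standard input paths", {
  sim <- simulate_dataset(small_sim_config(47))
  dir <- withr::local_tempdir()
  files <- write_sim_dataset(sim, dir)
  recs <- read_fasta(files[["clones_fasta"]])
  expect_length(recs, nrow(sim$clones))
  expect_equal(recs[[1]]$individual_id, sim$clones$individual_id[[1]])
  meta <- read_clone_metadata(files[["clones_tsv"]])
  expect_equal(meta$clone_id, sim$clones$clone_id)
  truth <- jsonlite::fromJSON(files[["truth_json"]])
  expect_equal(truth$n_loci, sim$truth$n_loci)
})
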