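test_that("site counts for benchmark codons match the single-change enumeration", {
  ttt <- ng86_site_counts("TTT")
  expect_equal(ttt[["s"]], 1 / 3)
  expect_equal(ttt[["n"]], 8 / 3)
  expect_equal(ng86_site_counts("TGG")[["s"]], 0)
  expect_error(ng86_site_counts("TAA"), "sense")
  expect_error(ng86_site_counts("ANA"), "sense")
})

test_that("site counts match the enumeration oracle for all 61 sense codons, both stop conventions", {
  sense <- setdiff(names(ORACLE_CODE), c("TAA", "TAG", "TGA"))
  for (conv in c("exclude", "nonsyn")) {
    for (cod in sense) {
      got <- ng86_site_counts(cod, stops = conv)
      want <- oracle_site_counts(cod, stops = conv)
      expect_equal(got[["s"]], want[["s"]], tolerance = 1e-12,
                   label = paste(cod, conv, "s"))
      expect_equal(got[["s"]] + got[["n"]], 3)
    }
  }
})

test_that("multi-hit codon differences average over stop-avoiding minimal pathways", {
  # TTT -> GTA: two pathways, one with a synonymous leg; average (0.5, 1.5)
  d <- mhcloci:::codon_path_diffs("TTT", "GTA")
  expect_equal(unname(d), c(0.5, 1.5))
  set.seed(51)
  sense <- setdiff(names(ORACLE_CODE), c("TAA", "TAG", "TGA"))
  for (i in 1:50) {
    pair <- sample(sense, 2)
    got <- mhcloci:::codon_path_diffs(pair[[1]], pair[[2]])
    want <- oracle_codon_diffs(pair[[1]], pair[[2]])
    expect_equal(unname(got), unname(want), tolerance = 1e-12,
                 label = paste(pair, collapse = "/"))
    # symmetry
    rev <- mhcloci:::codon_path_diffs(pair[[2]], pair[[1]])
    expect_equal(got, rev)
  }
})

test_that("pairwise NG86 distances behave on identity, single differences and the JC limit", {
  a <- strrep("ATG", 10)
  expect_equal(unlist(ng86_pairwise(a, a)[c("pS", "pN", "dS", "dN")]),
               c(pS = 0, pN = 0, dS = 0, dN = 0))

  # one synonymous difference: GGG -> GGA in a 10-codon pair
  x <- paste(rep("GGG", 10), collapse = "")
  y <- paste(c(rep("GGG", 9), "GGA"), collapse = "")
  p <- ng86_pairwise(x, y)
  S <- sum(vapply(rep("GGG", 10), function(cc) oracle_site_counts(cc)[["s"]], numeric(1)))
  S <- (S + S - oracle_site_counts("GGG")[["s"]] + oracle_site_counts("GGA")[["s"]]) / 2
  expect_equal(p$pN, 0)
  expect_equal(p$pS, 1 / S)
  expect_equal(p$dS, -0.75 * log(1 - 4 * p$pS / 3))

  expect_equal(jukes_cantor(0), 0)
  expect_true(is.na(jukes_cantor(0.8)))
  expect_error(ng86_pairwise("ATG", "ATGA"), "equal length")
})

test_that("codons with N or stops are dropped pairwise and reported", {
  x <- paste(c("ATG", "GGG", "TAA"), collapse = "")
  y <- paste(c("ATG", "GGN", "TAA"), collapse = "")
  p <- ng86_pairwise(x, y)
  expect_equal(p$n_dropped, 2L)   # the N codon and the stop codon
  expect_equal(p$S + p$N, 3)      # one usable codon left
})

test_that("the selection test is seeded, symmetric in its inputs and honest about identity", {
  cod <- simulate_neutral_codons(6, 50, 0.05, seed = 3)
  t1 <- selection_test(cod, n_bootstrap = 200, seed = 9)
  t2 <- selection_test(cod, n_bootstrap = 200, seed = 9)
  expect_identical(t1, t2)
  t3 <- selection_test(cod, n_bootstrap = 200, seed = 10)
  expect_false(identical(t1$Z, t3$Z))

  same <- matrix(rep(c("ATG", "GGA", "CCT"), each = 3), nrow = 3)
  res <- selection_test(same, n_bootstrap = 50, seed = 1)
  expect_false(res$applicable)
  expect_equal(res$dN, 0)
  expect_equal(res$dS, 0)

  expect_error(selection_test(cod, region = 1L), "at least 2 codons")
})

test_that("positive selection planted in the PBR is detected; neutral regions are not flagged", {
  detected <- logical(0)
  neutral_flagged <- logical(0)
  for (seed in 1:5) {
    sim <- simulate_dataset(small_sim_config(seed, pbr_multiplier = 8,
                                             allele_divergence = 0.02))
    pool <- sim_carried_alleles(sim, "cdna")
    if (length(unique(pool)) < 4) next
    orf <- find_orf(pool[[1]])
    cod <- codon_alignment(build_msa(pool), orf)
    al <- sim$truth$loci[[1]]$alleles[[1]]
    m <- spliced_align(seq_record("c", al$cdna), seq_record("g", al$gdna), min_exon = 15)
    reg <- partition_regions(m, "pbr_vs_rest")
    pbr <- selection_test(cod, reg$codons$PBR, n_bootstrap = 300, seed = seed)
    non <- selection_test(cod, reg$codons$nonPBR, n_bootstrap = 300, seed = seed)
    detected <- c(detected, isTRUE(pbr$p < 0.05))
    neutral_flagged <- c(neutral_flagged, isTRUE(non$p < 0.05))
    # dN exceeds dS in the region where nonsynonymous changes are favoured
    expect_gt(pbr$dN, pbr$dS)
  }
  expect_gte(sum(detected), ceiling(length(detected) * 0.6))
  expect_lte(sum(neutral_flagged), 1)
})
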