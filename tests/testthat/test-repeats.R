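test_that("pure short repeats are called with exact span, copies and canonical unit", {
  r <- find_tandem_repeats("ACACAC")
  expect_equal(nrow(r), 1L)
  expect_equal(r$unit, "AC")
  expect_equal(r$copies, 3)
  expect_equal(r$purity, 1)
  expect_equal(c(r$start, r$end), c(0L, 6L))

  dec <- find_tandem_repeats("GTCCAGTTGAGTCCAGTTGA")
  expect_equal(nrow(dec), 1L)
  expect_equal(dec$unit_len, 10L)
  expect_equal(dec$copies, 2)
  expect_equal(dec$unit, "AGTCCAGTTG")   # canonical rotation of GTCCAGTTGA
})

test_that("reporting is invariant to the phase at which a tract is entered", {
  a <- find_tandem_repeats(strrep("GTCCAGTTGA", 3))
  b <- find_tandem_repeats(strrep("CCAGTTGAGT", 3))
  expect_equal(a$unit, b$unit)
  expect_equal(a$copies, b$copies)
  expect_equal(a$copies, 3)
})

test_that("homopolymers are reported only at high copy number", {
  expect_equal(nrow(find_tandem_repeats("GGGGG")), 0L)
  r <- find_tandem_repeats("GGGGGGG")
  expect_equal(nrow(r), 1L)
  expect_equal(r$unit, "G")
  expect_equal(r$copies, 7)
})

test_that("planted repeats in random sequence are recovered at full purity and span", {
  set.seed(11)
  for (rep in 1:40) {
    u_len <- sample(2:16, 1)
    unit <- random_dna(u_len)
    copies <- sample(2:8, 1)
    # skip units that are themselves periodic (e.g. "AA", "ACAC"): the
    # detector rightly reports those at their shorter fundamental period
    pre <- find_tandem_repeats(strrep(unit, copies), min_copies = 2)
    if (nrow(pre) != 1 || pre$unit_len != u_len) next
    # in isolation the detected span is exact, at purity 1
    tract <- strrep(unit, copies)
    exact <- find_tandem_repeats(tract, min_copies = 2)
    exact <- exact[exact$unit == canonical_rotation_test(unit), , drop = FALSE]
    expect_equal(nrow(exact), 1L)
    expect_equal(c(exact$start, exact$end), c(0L, nchar(tract)))
    expect_equal(exact$purity, 1)
    expect_equal(exact$copies, copies)

    # embedded in random flanks the tract is still found; coincidental
    # periodicity in the flanks may stretch the call by up to one unit
    s <- paste0(random_dna(30), tract, random_dna(30))
    calls <- find_tandem_repeats(s, min_copies = 2)
    hit <- calls[calls$unit == canonical_rotation_test(unit), , drop = FALSE]
    expect_gte(nrow(hit), 1L)
    best <- hit[which.max(hit$end - hit$start), ]
    expect_lte(best$start, 30L + u_len)
    expect_gte(best$end, 30L + nchar(tract) - u_len)
    expect_gte(best$purity, 0.85)
    expect_true(best$start >= 0 && best$end <= nchar(s))
  }
})

test_that("intron tables report per-allele lengths and dominant repeats", {
  sim <- simulate_dataset(small_sim_config(17))
  models <- list()
  gseqs <- list()
  for (l in 1:2) {
    al <- sim$truth$loci[[l]]$alleles[[1]]
    nm <- al$name
    models[[nm]] <- spliced_align(seq_record(nm, al$cdna), seq_record(nm, al$gdna),
                                  min_exon = 15)
    gseqs[[nm]] <- al$gdna
  }
  tab <- intron_length_table(models, gseqs)
  expect_equal(nrow(tab), 2L * 5L)
  # length differences between loci equal unit length x copy-number difference
  cfg <- sim$truth$config
  for (i in seq_along(cfg$intron_base_lengths)) {
    lens <- tab$length[tab$intron == i]
    c1 <- sim$truth$loci[[1]]$intron_copies[[i]]
    c2 <- sim$truth$loci[[2]]$intron_copies[[i]]
    u <- cfg$intron_repeat_units[[i]]
    expected_diff <- if (is.na(u)) 0L else nchar(u) * (c1 - c2)
    expect_equal(lens[[1]] - lens[[2]], expected_diff)
  }
  # the planted decamer dominates intron 3
  expect_equal(tab$dominant_unit[tab$intron == 3 & tab$allele == names(models)[1]],
               canonical_rotation_test("GTCCAGTTGA"))
})

test_that("intronless models give an empty table and mixed exon counts are rejected", {
  s <- seq_record("x", "ATGAAACCCGGGTTTAAACCCGGGTTTTAA")
  m1 <- spliced_align(s, seq_record("g", s$residues), min_exon = 5)
  expect_equal(nrow(intron_length_table(list(x = m1), list(x = s$residues))), 0L)

  sim <- simulate_dataset(small_sim_config(19))
  al <- sim$truth$loci[[1]]$alleles[[1]]
  m6 <- spliced_align(seq_record("c", al$cdna), seq_record("g", al$gdna), min_exon = 15)
  expect_error(
    intron_length_table(list(a = m1, b = m6), list(a = s$residues, b = al$gdna)),
    "mixed exon counts"
  )
})
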