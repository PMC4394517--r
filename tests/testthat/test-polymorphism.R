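test_that("equal-length inputs stack into a gap-free alignment", {
  m <- build_msa(c(a = "ACGT", b = "ACGT", c = "ACTT"))
  expect_s3_class(m, "msa")
  expect_equal(m$ncol, 4L)
  expect_false(any(grepl("-", m$aligned, fixed = TRUE)))
  expect_error(build_msa(c(a = "ACGT")), "at least 2")
})

test_that("unequal-length alignment is optimal against exhaustive enumeration", {
  m <- build_msa(c(a = "ACGT", b = "ACT"))
  gaps <- sum(grepl("-", strsplit(paste(m$aligned, collapse = ""), "")[[1]]))
  expect_equal(gaps, 1L)  # exactly one gap column
  # removing gaps reproduces the inputs
  expect_equal(gsub("-", "", m$aligned), c("ACGT", "ACT"))

  oracle <- oracle_align_enum("ACGT", "ACT")
  expect_true(any(vapply(oracle$alignments, function(al) {
    identical(c(al$a, al$b), m$aligned)
  }, logical(1))))

  set.seed(31)
  for (i in 1:10) {
    a <- random_dna(sample(3:6, 1))
    b <- random_dna(sample(3:6, 1))
    m2 <- build_msa(c(a = a, b = b))
    if (m2$ncol == max(nchar(a), nchar(b)) && nchar(a) == nchar(b)) next
    ora <- oracle_align_enum(a, b)
    # package alignment must reach the enumerated optimum score
    sc <- oracle_align_enum(gsub("-", "", m2$aligned[1]), gsub("-", "", m2$aligned[2]))
    expect_equal(sc$score, ora$score)
  }
})

test_that("polymorphic site counting matches the column definition", {
  m0 <- build_msa(c(a = "ACGT", b = "ACGT"))
  expect_equal(polymorphic_sites(m0)$total, 0L)

  m1 <- build_msa(c(a = "AAA", b = "AAT", c = "AAC"))
  expect_equal(polymorphic_sites(m1)$total, 1L)

  regions <- list(left = c(0L, 2L), right = c(2L, 3L))
  pr <- polymorphic_sites(m1, regions)
  expect_equal(unname(pr$per_region), c(0L, 1L))
  expect_equal(sum(pr$per_region), pr$total)
  expect_error(polymorphic_sites(m1, list(bad = c(0L, 9L))), "outside")

  # gap columns are judged on their non-gap residues
  mg <- structure(list(seq_id = c("a", "b"), aligned = c("A-G", "ATG"), ncol = 3L),
                  class = "msa")
  expect_equal(polymorphic_sites(mg)$total, 0L)
})

test_that("substitutions are classified and named in 1-based ORF coordinates", {
  orf_codons <- c("ATG", rep("GAA", 100), "TAA")  # E at codons 2..101
  ref <- paste0("GGGGG", paste(orf_codons, collapse = ""))
  orf <- find_orf(ref)
  expect_equal(orf$start, 5L)

  expect_equal(nrow(classify_substitutions(ref, ref, orf)), 0L)

  # GAA -> GGA at protein position 74: E74G, ORF position 3*73 + 2 = 221
  alt <- ref
  substr(alt, 5L + 73L * 3L + 2L, 5L + 73L * 3L + 2L) <- "G"
  rec <- classify_substitutions(ref, alt, orf)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$kind, "nonsynonymous")
  expect_equal(rec$protein_notation, "E74G")
  expect_equal(rec$cdna_notation, "221A>G")

  # GAA -> GAG at codon 10 is synonymous: no protein notation
  alt2 <- ref
  substr(alt2, 5L + 9L * 3L + 3L, 5L + 9L * 3L + 3L) <- "G"
  rec2 <- classify_substitutions(ref, alt2, orf)
  expect_equal(rec2$kind, "synonymous")
  expect_true(is.na(rec2$protein_notation))
  expect_equal(rec2$cdna_notation, "30A>G")

  expect_error(classify_substitutions("AAA", "AAAA", orf), "equal length")
})

test_that("substitution kinds agree with a translate-and-compare oracle on random mutagenesis", {
  set.seed(41)
  orf_codons <- c("ATG", sample(setdiff(names(ORACLE_CODE), c("TAA", "TAG", "TGA")),
                                60, replace = TRUE), "TAA")
  ref <- paste(orf_codons, collapse = "")
  orf <- find_orf(ref)
  n_checked <- 0L
  for (i in 1:300) {
    pos <- sample(4:(nchar(ref) - 3), 1)
    old <- substr(ref, pos, pos)
    alt <- ref
    substr(alt, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    # skip cases where the mutation breaks the ORF itself (premature stop)
    rec <- classify_substitutions(ref, alt, orf)
    if (nrow(rec) != 1L) next
    same_protein <- identical(oracle_translate(substr(ref, orf$start + 1, orf$end)),
                              oracle_translate(substr(alt, orf$start + 1, orf$end)))
    expect_equal(rec$kind == "synonymous", same_protein)
    expect_equal(ceiling(rec$orf_pos / 3),
                 as.integer(sub("^[A-Z*](\\d+).*$", "\\1",
                                ifelse(is.na(rec$protein_notation),
                                       paste0("X", ceiling(rec$orf_pos / 3), "X"),
                                       rec$protein_notation))))
    n_checked <- n_checked + 1L
  }
  expect_gt(n_checked, 250L)
})
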