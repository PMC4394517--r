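# Independent oracles used by the tests. Each is deliberately written as a
# naive brute-force or hard-coded reference, sharing no code with the
# package internals it checks.

# Hard-coded standard genetic code (independent of the table the package
# uses). Stop codons map to "*".
ORACLE_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

oracle_translate <- function(dna) {
  n <- nchar(dna) %/% 3L
  if (n == 0L) return("")
  cods <- substring(dna, seq(1, by = 3, length.out = n), seq(3, by = 3, length.out = n))
  aa <- ORACLE_CODE[cods]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# Brute-force ORF scan: every ATG paired with every downstream in-frame
# stop; the shortest stop wins per ATG; then the longest ORF overall, ties
# to the smallest start. Returns c(start, end) 0-based half-open, or NULL.
oracle_orf <- function(dna) {
  n <- nchar(dna)
  best <- NULL
  for (s in seq_len(max(0L, n - 5L))) {
    if (substr(dna, s, s + 2) != "ATG") next
    e <- s + 3L
    while (e + 2L <= n) {
      cod <- substr(dna, e, e + 2L)
      if (cod %in% c("TAA", "TAG", "TGA")) {
        len <- e + 3L - s
        if (is.null(best) || len > best[[2]] - best[[1]]) best <- c(s - 1L, e + 2L)
        break
      }
      e <- e + 3L
    }
  }
  best
}

# Enumerated NG86 site counts: all 9 single-base neighbours, stop
# neighbours dropped from the per-position denominator.
oracle_site_counts <- function(codon, stops = "exclude") {
  s <- 0
  for (pos in 1:3) {
    syn <- 0; tot <- 0
    for (b in c("A", "C", "G", "T")) {
      if (b == substr(codon, pos, pos)) next
      mut <- codon
      substr(mut, pos, pos) <- b
      if (ORACLE_CODE[[mut]] == "*") {
        if (stops == "nonsyn") tot <- tot + 1
        next
      }
      tot <- tot + 1
      if (ORACLE_CODE[[mut]] == ORACLE_CODE[[codon]]) syn <- syn + 1
    }
    if (tot > 0) s <- s + syn / tot
  }
  c(s = s, n = 3 - s)
}

# Pathway-enumeration oracle for per-codon-pair difference counts.
oracle_codon_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(c(sd = 0, nd = 0))
  perms <- if (length(pos) == 1L) list(pos) else {
    do.call(c, lapply(seq_along(pos), function(i) {
      lapply(oracle_perms(pos[-i]), function(rest) c(pos[[i]], rest))
    }))
  }
  run <- function(skip_stops) {
    tot <- c(sd = 0, nd = 0); np <- 0
    for (ord in perms) {
      cur <- c1; sd <- 0; nd <- 0; ok <- TRUE
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (skip_stops && ORACLE_CODE[[nxt]] == "*") { ok <- FALSE; break }
        if (ORACLE_CODE[[cur]] == ORACLE_CODE[[nxt]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      if (ok) { tot <- tot + c(sd = sd, nd = nd); np <- np + 1 }
    }
    list(tot = tot, np = np)
  }
  r <- run(TRUE)
  if (r$np == 0) r <- run(FALSE)
  r$tot / r$np
}

oracle_perms <- function(x) {
  if (length(x) <= 1L) return(list(x))
  do.call(c, lapply(seq_along(x), function(i) {
    lapply(oracle_perms(x[-i]), function(rest) c(x[[i]], rest))
  }))
}

# Exhaustive global alignment of two short sequences under affine gap
# scoring (match/mismatch/open/extend); returns the optimal score and all
# optimal alignments as list(a=, b=) of gapped strings.
oracle_align_enum <- function(a, b, match = 1, mismatch = -1, open = 5, extend = 1) {
  best <- new.env()
  best$score <- -Inf
  best$alns <- list()
  score_aln <- function(ra, rb) {
    s <- 0
    in_gap_a <- FALSE; in_gap_b <- FALSE
    for (k in seq_len(nchar(ra))) {
      ca <- substr(ra, k, k); cb <- substr(rb, k, k)
      if (ca == "-") {
        s <- s - extend - if (in_gap_a) 0 else open
        in_gap_a <- TRUE; in_gap_b <- FALSE
      } else if (cb == "-") {
        s <- s - extend - if (in_gap_b) 0 else open
        in_gap_b <- TRUE; in_gap_a <- FALSE
      } else {
        s <- s + if (ca == cb) match else mismatch
        in_gap_a <- in_gap_b <- FALSE
      }
    }
    s
  }
  recurse <- function(i, j, ra, rb) {
    if (i > nchar(a) && j > nchar(b)) {
      sc <- score_aln(ra, rb)
      if (sc > best$score) { best$score <- sc; best$alns <- list() }
      if (sc == best$score) best$alns[[length(best$alns) + 1L]] <- list(a = ra, b = rb)
      return()
    }
    if (i <= nchar(a) && j <= nchar(b)) {
      recurse(i + 1L, j + 1L, paste0(ra, substr(a, i, i)), paste0(rb, substr(b, j, j)))
    }
    if (i <= nchar(a)) recurse(i + 1L, j, paste0(ra, substr(a, i, i)), paste0(rb, "-"))
    if (j <= nchar(b)) recurse(i, j + 1L, paste0(ra, "-"), paste0(rb, substr(b, j, j)))
  }
  recurse(1L, 1L, "", "")
  list(score = best$score, alignments = best$alns)
}

# Brute-force minimum number of groups over all set partitions subject to
# the diploid constraint. `inc` is an allele x individual 0/1 matrix.
oracle_min_groups <- function(inc) {
  n <- nrow(inc)
  best <- n
  recurse <- function(i, blocks) {
    if (i > n) {
      best <<- min(best, length(blocks))
      return()
    }
    for (b in seq_along(blocks)) {
      if (any(colSums(inc[c(blocks[[b]], i), , drop = FALSE]) > 2L)) next
      nb <- blocks; nb[[b]] <- c(nb[[b]], i)
      recurse(i + 1L, nb)
    }
    recurse(i + 1L, c(blocks, list(i)))
  }
  recurse(1L, list())
  best
}

canonical_rotation_test <- function(unit) {
  n <- nchar(unit)
  rots <- vapply(seq_len(n), function(i) {
    paste0(substr(unit, i, n), substr(unit, 1, i - 1))
  }, character(1))
  min(rots)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

# Small, fast simulator configuration used where full study-scale data is
# not needed.
small_sim_config <- function(seed, ...) {
  args <- list(
    n_loci = 2L, n_individuals = 3L, alleles_per_locus = 3L,
    exon_lengths = c(40L, 60L, 63L, 30L, 25L, 40L),
    utr5_len = 12L, utr3_len = 12L,
    intron_base_lengths = c(40L, 30L, 30L, 24L, 30L),
    clone_depth = c(3L, 5L),
    seed = seed
  )
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}
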