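#' Multiple sequence alignment container
#'
#' Rows of equal length over `A/C/G/T/N/-`; removing the gaps from a row
#' reproduces the input sequence. Equal-length inputs (the usual case for
#' same-gene allele sets) are stacked without alignment; unequal-length
#' inputs go through progressive global alignment: each sequence is aligned
#' pairwise (dynamic programming, match +1, mismatch -1, gap open -5, gap
#' extend -1, via [Biostrings::pairwiseAlignment()]) against the first
#' sequence, and the pairwise alignments are merged star-wise under the
#' once-a-gap-always-a-gap rule, in input order.
#'
#' @param seqs List of dna [seq_record]s or a named character vector;
#'   at least 2 sequences.
#' @param match,mismatch,gap_open,gap_extend Alignment scoring constants;
#'   the defaults suit near-identical allele sets, for which any sane
#'   scheme yields the same alignment.
#' @return An object of class `msa`: list with `seq_id`, `aligned`
#'   (character vector of equal-length rows) and `ncol`.
#' @export
build_msa <- function(seqs, match = 1, mismatch = -1, gap_open = 5, gap_extend = 1) {
  strings <- as_seq_strings(seqs)
  if (length(strings) < 2L) stop("build_msa requires at least 2 sequences")
  ids <- names(strings)
  lens <- nchar(strings)
  if (length(unique(lens)) == 1L) {
    return(new_msa(ids, unname(strings)))
  }
  ref <- strings[[1L]]
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match, mismatch = mismatch,
                                                  baseOnly = FALSE, type = "DNA")
  pair_rows <- vector("list", length(strings))
  for (i in seq_along(strings)[-1L]) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = strings[[i]], subject = ref,
      type = "global", substitutionMatrix = mat,
      gapOpening = gap_open, gapExtension = gap_extend
    )
    pair_rows[[i]] <- list(
      q = as.character(Biostrings::alignedPattern(pa)),
      r = as.character(Biostrings::alignedSubject(pa))
    )
  }
  merged <- merge_star(ref, pair_rows[-1L])
  new_msa(ids, c(merged$ref, merged$rows))
}

as_seq_strings <- function(seqs) {
  if (is.character(seqs)) {
    stopifnot(!is.null(names(seqs)))
    return(toupper(seqs))
  }
  seq_strings(seqs)
}

new_msa <- function(ids, rows) {
  stopifnot(length(unique(nchar(rows))) == 1L)
  structure(list(seq_id = ids, aligned = rows, ncol = nchar(rows[[1L]])), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences x %d columns\n", length(x$seq_id), x$ncol))
  invisible(x)
}

# Star merge of pairwise alignments against a common reference.
# Each element of `pairs` is list(q = aligned query, r = aligned reference).
merge_star <- function(ref, pairs) {
  m <- nchar(ref)
  # insertion counts after reference position j (j = 0..m) for each pair
  ins <- lapply(pairs, function(p) {
    rch <- strsplit(p$r, "")[[1]]
    counts <- integer(m + 1L)
    j <- 0L
    for (ch in rch) {
      if (ch == "-") counts[[j + 1L]] <- counts[[j + 1L]] + 1L else j <- j + 1L
    }
    counts
  })
  master <- if (length(ins)) do.call(pmax, ins) else integer(m + 1L)
  ref_ch <- strsplit(ref, "")[[1]]
  ref_row <- character(0)
  for (j in 0:m) {
    ref_row <- c(ref_row, rep("-", master[[j + 1L]]), if (j < m) ref_ch[[j + 1L]])
  }
  rows <- vapply(seq_along(pairs), function(i) {
    qch <- strsplit(pairs[[i]]$q, "")[[1]]
    rch <- strsplit(pairs[[i]]$r, "")[[1]]
    out <- character(0)
    j <- 0L           # reference position consumed
    used <- 0L        # insertion slots consumed at current j
    for (k in seq_along(rch)) {
      if (rch[[k]] == "-") {
        out <- c(out, qch[[k]])
        used <- used + 1L
      } else {
        out <- c(out, rep("-", master[[j + 1L]] - used), qch[[k]])
        used <- 0L
        j <- j + 1L
      }
    }
    out <- c(out, rep("-", master[[m + 1L]] - used))
    paste(out, collapse = "")
  }, character(1))
  list(ref = paste(ref_row, collapse = ""), rows = rows)
}

msa_matrix <- function(msa) {
  do.call(rbind, strsplit(msa$aligned, ""))
}

#' Count polymorphic sites in an alignment
#'
#' A column is polymorphic when it contains at least two distinct non-gap
#' bases; columns containing gaps are judged on their non-gap residues.
#'
#' @param msa An [build_msa()] result.
#' @param regions Optional `region_partition` (or a named list of 0-based
#'   half-open column intervals, possibly several rows each); per-region
#'   counts are reported alongside the total. Region intervals must lie
#'   within the alignment.
#' @return List with `total` and, when `regions` is given, `per_region`
#'   (named integer vector). Per-region counts sum to the total whenever
#'   the regions cover the alignment.
#' @export
polymorphic_sites <- function(msa, regions = NULL) {
  mat <- msa_matrix(msa)
  poly <- apply(mat, 2L, function(col) {
    b <- unique(col[col != "-"])
    length(b) >= 2L
  })
  out <- list(total = sum(poly))
  if (!is.null(regions)) {
    intervals <- if (inherits(regions, "region_partition")) regions$intervals else regions
    out$per_region <- vapply(intervals, function(iv) {
      iv <- rbind(iv)
      cols <- unlist(lapply(seq_len(nrow(iv)), function(r) {
        s <- iv[r, 1L]; e <- iv[r, 2L]
        if (s < 0L || e > msa$ncol) stop("region interval [", s, ",", e, ") outside alignment")
        if (e > s) seq.int(s + 1L, e) else integer(0)
      }))
      sum(poly[cols])
    }, integer(1))
  }
  out
}

#' Classify substitutions between two equal-length sequences
#'
#' Compares the open reading frames of a reference and an alternative
#' sequence position by position and classifies each difference as
#' synonymous or nonsynonymous by translating the affected codon.
#' Nomenclature follows biological 1-based numbering from the ORF start:
#' `242A>G` for a cDNA change, `E74G` for the encoded replacement
#' (protein position = ceiling(ORF position / 3), counted from the
#' initiator Met).
#'
#' @param ref,alt dna [seq_record]s of equal length; differences must be
#'   substitutions only.
#' @param orf [find_orf()] annotation for `ref` (assumed to hold for `alt`).
#' @return Data.frame with one row per differing ORF position: `orf_pos`
#'   (1-based), `cdna_pos` (1-based from the 5' end), `ref_base`,
#'   `alt_base`, `kind`, `cdna_notation`, `protein_notation` (`NA` for
#'   synonymous changes).
#' @export
classify_substitutions <- function(ref, alt, orf) {
  r <- if (inherits(ref, "seq_record")) ref$residues else toupper(ref)
  a <- if (inherits(alt, "seq_record")) alt$residues else toupper(alt)
  if (nchar(r) != nchar(a)) stop("ref and alt must have equal length")
  stopifnot(isTRUE(orf$found))
  rc <- strsplit(r, "")[[1]]
  ac <- strsplit(a, "")[[1]]
  diff <- which(rc != ac)
  diff <- diff[diff > orf$start & diff <= orf$end]   # 1-based positions in ORF
  if (!length(diff)) {
    return(data.frame(orf_pos = integer(0), cdna_pos = integer(0),
                      ref_base = character(0), alt_base = character(0),
                      kind = character(0), cdna_notation = character(0),
                      protein_notation = character(0), stringsAsFactors = FALSE))
  }
  orf_pos <- diff - orf$start
  codon_idx <- (orf_pos - 1L) %/% 3L + 1L
  codon_start <- orf$start + (codon_idx - 1L) * 3L + 1L
  ref_codon <- substring(r, codon_start, codon_start + 2L)
  alt_codon <- substring(a, codon_start, codon_start + 2L)
  ref_aa <- translate_codons(ref_codon)
  alt_aa <- translate_codons(alt_codon)
  syn <- ref_aa == alt_aa
  data.frame(
    orf_pos = orf_pos,
    cdna_pos = diff,
    ref_base = rc[diff],
    alt_base = ac[diff],
    kind = ifelse(syn, "synonymous", "nonsynonymous"),
    cdna_notation = sprintf("%d%s>%s", orf_pos, rc[diff], ac[diff]),
    protein_notation = ifelse(syn, NA_character_,
                              sprintf("%s%d%s", ref_aa, codon_idx, alt_aa)),
    stringsAsFactors = FALSE
  )
}

#' Write an alignment as aligned FASTA
#' @param msa An `msa` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msa_fasta <- function(msa, path) {
  records <- lapply(seq_along(msa$seq_id), function(i) {
    structure(list(seq_id = msa$seq_id[[i]], description = "",
                   residues = msa$aligned[[i]], moltype = "dna",
                   individual_id = NA_character_),
              class = "seq_record")
  })
  headers <- msa$seq_id
  set <- Biostrings::BStringSet(msa$aligned)
  names(set) <- headers
  Biostrings::writeXStringSet(set, filepath = path, width = 70L)
  invisible(path)
}

#' Codon matrix of the ORF columns of an alignment
#'
#' @param msa A gap-free `msa` (alleles of one gene, equal length).
#' @param orf ORF annotation valid for every row.
#' @return Character matrix, rows = sequences, columns = ORF codons
#'   (including the terminal stop codon).
#' @export
codon_alignment <- function(msa, orf) {
  stopifnot(isTRUE(orf$found))
  if (any(grepl("-", msa$aligned, fixed = TRUE))) {
    stop("codon_alignment requires a gap-free alignment")
  }
  orf_rows <- substring(msa$aligned, orf$start + 1L, orf$end)
  mat <- do.call(rbind, lapply(orf_rows, split_codons))
  rownames(mat) <- msa$seq_id
  mat
}
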