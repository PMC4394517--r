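#' Detect tandem repeats by period autocorrelation
#'
#' For every candidate unit length u up to `max_unit`, positions where a
#' base equals the base u positions earlier are self-matches; maximal runs
#' of self-matches (extended across short interruptions while the overall
#' fraction of matching bases stays at or above `min_purity`) delimit
#' candidate repeat tracts. Overlapping calls of different periods are
#' resolved by keeping the call with the higher purity x span product,
#' ties going to the shorter unit, so a pure dinucleotide tract is reported
#' once as a dinucleotide and not again as a tetranucleotide. The unit is
#' reported in canonical rotation (lexicographically smallest), making the
#' output invariant to the phase at which a tract is entered.
#'
#' This is a deliberately simple self-match detector, not a reimplementation
#' of alignment-scored repeat finders; the microsatellites that drive
#' locus-diagnostic intron length variation (GT dinucleotides, the
#' GTCCAGTTGA decamer, the ACCTGTCTGTCTGCTC 16-mer) are short and
#' near-perfect, which this model captures.
#'
#' @param seq A dna [seq_record] or nucleotide string.
#' @param max_unit Maximum unit length considered (1-20).
#' @param min_copies Minimum (fractional) copy number reported.
#' @param min_purity Minimum fraction of self-matching bases in a tract.
#' @param min_homopolymer_copies Homopolymer tracts (unit length 1) are
#'   reported only at or above this copy number, to cut noise.
#' @return Data.frame with one row per repeat: `start`, `end` (0-based
#'   half-open), `unit` (canonical rotation), `unit_len`, `copies`
#'   (= span / unit length), `purity`.
#' @export
find_tandem_repeats <- function(seq, max_unit = 20L, min_copies = 2.0,
                                min_purity = 0.85, min_homopolymer_copies = 6) {
  s <- if (inherits(seq, "seq_record")) seq$residues else toupper(seq)
  n <- nchar(s)
  x <- strsplit(s, "")[[1]]
  calls <- list()
  for (u in seq_len(min(max_unit, max(0L, n - 1L)))) {
    idx <- (u + 1L):n
    match_u <- x[idx] == x[idx - u]
    runs <- purity_runs(match_u, min_purity)
    for (r in runs) {
      a <- r[[1]]; b <- r[[2]]          # indices into match_u (= sequence start)
      span_start <- a
      span_end <- b + u
      span <- span_end - span_start + 1L
      copies <- span / u
      # extract the unit from the purest stretch, so a mutated first copy
      # does not distort the reported motif
      unit <- substr(s, r[[4]], r[[4]] + u - 1L)
      homopolymer <- length(unique(strsplit(unit, "")[[1]])) == 1L
      if (homopolymer) {
        # a homopolymer tract shows up at every period; gate it on total
        # length regardless of the nominal unit
        if (span < min_homopolymer_copies || copies < min_copies) next
      } else if (copies < min_copies) next
      purity <- r[[3]]
      calls[[length(calls) + 1L]] <- list(
        start = span_start - 1L, end = span_end, unit = canonical_rotation(unit),
        unit_len = u, copies = copies, purity = purity
      )
    }
  }
  if (!length(calls)) {
    return(data.frame(start = integer(0), end = integer(0), unit = character(0),
                      unit_len = integer(0), copies = numeric(0), purity = numeric(0),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, lapply(calls, as.data.frame, stringsAsFactors = FALSE))
  # overlap resolution: higher purity x span first, ties to shorter unit
  score <- df$purity * (df$end - df$start)
  ord <- order(-score, df$unit_len, df$start)
  df <- df[ord, , drop = FALSE]
  kept <- logical(0)
  keep_rows <- integer(0)
  for (i in seq_len(nrow(df))) {
    overlap <- FALSE
    for (j in keep_rows) {
      if (df$start[[i]] < df$end[[j]] && df$start[[j]] < df$end[[i]]) { overlap <- TRUE; break }
    }
    if (!overlap) keep_rows <- c(keep_rows, i)
  }
  df <- df[keep_rows, , drop = FALSE]
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Maximal tracts of TRUE in `m`, greedily extended rightward across FALSE
# gaps while the match fraction stays >= min_purity. Returns a list of
# list(start, end, purity, longest_pure_start) in indices of m.
purity_runs <- function(m, min_purity) {
  runs <- list()
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  true_runs <- which(r$values)
  consumed <- 0L
  for (tr in true_runs) {
    if (starts[[tr]] <= consumed) next
    a <- starts[[tr]]
    b <- ends[[tr]]
    matches <- r$lengths[[tr]]
    best_pure <- c(starts[[tr]], r$lengths[[tr]])
    k <- tr
    while (k + 2L <= length(r$lengths)) {
      gap <- r$lengths[[k + 1L]]
      nxt <- r$lengths[[k + 2L]]
      if ((matches + nxt) / (b - a + 1L + gap + nxt) >= min_purity) {
        matches <- matches + nxt
        b <- ends[[k + 2L]]
        k <- k + 2L
        if (nxt > best_pure[[2]]) best_pure <- c(starts[[k]], nxt)
      } else break
    }
    runs[[length(runs) + 1L]] <- list(a, b, matches / (b - a + 1L), best_pure[[1]])
    consumed <- b
  }
  runs
}

canonical_rotation <- function(unit) {
  n <- nchar(unit)
  if (n <= 1L) return(unit)
  doubled <- paste0(unit, unit)
  rots <- substring(doubled, seq_len(n), seq_len(n) + n - 1L)
  min(rots)
}

#' Tandem-repeat calls across a set of sequences
#'
#' Convenience wrapper running [find_tandem_repeats()] over several
#' sequences and stacking the calls with a `seq_id` column -- the layout
#' of the repeats TSV the pipeline writes.
#'
#' @param seqs Named character vector or list of dna [seq_record]s.
#' @param ... Passed to [find_tandem_repeats()].
#' @return Data.frame `seq_id`, `start`, `end`, `unit`, `copies`,
#'   `purity`.
#' @export
repeats_table <- function(seqs, ...) {
  strings <- as_seq_strings(seqs)
  rows <- lapply(names(strings), function(nm) {
    df <- find_tandem_repeats(strings[[nm]], ...)
    if (nrow(df)) cbind(seq_id = nm, df[c("start", "end", "unit", "copies", "purity")])
    else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(seq_id = character(0), start = integer(0), end = integer(0),
                      unit = character(0), copies = numeric(0), purity = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Tabulate intron lengths and dominant repeats across alleles
#'
#' The locus-diagnostic signal of the gene family: intron lengths differ
#' between loci largely through tandem-repeat copy number, so a table of
#' per-allele, per-intron lengths annotated with the dominant repeat makes
#' the length disparity interpretable.
#'
#' @param models Named list of `gene_model`s (one per allele), all with
#'   the same exon count.
#' @param gdna Named list (or vector) of the genomic sequences the models
#'   annotate, keyed like `models`.
#' @param grouping Optional `locus_grouping`; adds a `group` column.
#' @param ... Passed to [find_tandem_repeats()].
#' @return Data.frame with columns `allele`, `group`, `intron`, `length`,
#'   `dominant_unit` (canonical rotation, or `"none"`), `copies`.
#' @export
intron_length_table <- function(models, gdna, grouping = NULL, ...) {
  stopifnot(length(models) > 0L, !is.null(names(models)))
  exon_counts <- vapply(models, function(m) nrow(m$exons), integer(1))
  if (length(unique(exon_counts)) > 1L) {
    bad <- names(models)[exon_counts != stats::median(exon_counts)]
    stop("mixed exon counts across models; offending allele(s): ",
         paste(bad, collapse = ", "))
  }
  group_of <- function(allele) {
    if (is.null(grouping)) return(NA_character_)
    for (i in seq_along(grouping$groups)) {
      if (allele %in% grouping$groups[[i]]) return(paste0("group", i))
    }
    if (allele %in% grouping$unassigned) return("unassigned")
    NA_character_
  }
  rows <- list()
  for (nm in names(models)) {
    g <- gdna[[nm]]
    rec <- if (inherits(g, "seq_record")) g else seq_record(nm, g)
    introns <- extract_introns(models[[nm]], rec)
    if (nrow(introns) == 0L) next
    for (i in seq_len(nrow(introns))) {
      reps <- find_tandem_repeats(introns$residues[[i]], ...)
      if (nrow(reps)) {
        top <- reps[which.max(reps$end - reps$start), ]
        unit <- top$unit; copies <- top$copies
      } else {
        unit <- "none"; copies <- NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        allele = nm, group = group_of(nm),
        intron = introns$intron[[i]], length = introns$length[[i]],
        dominant_unit = unit, copies = copies,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(allele = character(0), group = character(0), intron = integer(0),
                      length = integer(0), dominant_unit = character(0), copies = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
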