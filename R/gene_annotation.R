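#' Gene models: exon/intron annotation of a genomic allele
#'
#' A `gene_model` records where the exons of a genomic allele lie, obtained
#' by spliced alignment of the allele's cDNA (see [spliced_align()]). All
#' internal coordinates are 0-based half-open; user-facing exports (GFF3)
#' are 1-based inclusive.
#'
#' Invariants enforced by [validate_gene_model()]:
#' * exons are sorted, non-overlapping and non-empty;
#' * concatenating the genomic exon substrings reproduces the cDNA exactly
#'   (when the mismatch budget is 0);
#' * every intron starts with `GT` and ends with `AG`;
#' * there is exactly one intron fewer than exons.
#'
#' @name gene_model
NULL

new_gene_model <- function(genomic_id, cdna_id, exons, cdna_len, orf, mismatches = 0L) {
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  k <- nrow(exons)
  introns <- if (k > 1L) {
    cbind(start = exons[-k, "end"], end = exons[-1L, "start"])
  } else {
    matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end")))
  }
  utr5 <- if (orf$found) orf$start else NA_integer_
  utr3 <- if (orf$found) cdna_len - orf$end else NA_integer_
  structure(
    list(
      genomic_id = genomic_id, cdna_id = cdna_id,
      exons = exons, introns = introns,
      cdna_len = as.integer(cdna_len),
      utr5_len = utr5, utr3_len = utr3,
      orf = orf, mismatches = as.integer(mismatches)
    ),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf(
    "<gene_model> %s annotated by cDNA %s: %d exon(s), %d intron(s)\n",
    x$genomic_id, x$cdna_id, nrow(x$exons), nrow(x$introns)
  ))
  widths <- x$exons[, "end"] - x$exons[, "start"]
  cat("  exon lengths: ", paste(widths, collapse = ", "), " nt\n", sep = "")
  if (nrow(x$introns)) {
    iw <- x$introns[, "end"] - x$introns[, "start"]
    cat("  intron lengths: ", paste(iw, collapse = ", "), " nt\n", sep = "")
  }
  if (isTRUE(x$orf$found)) {
    cat(sprintf("  cDNA: 5'UTR %d nt | ORF %d nt | 3'UTR %d nt\n",
                x$utr5_len, x$orf$end - x$orf$start, x$utr3_len))
  }
  invisible(x)
}

#' Validate a gene model against its sequences
#'
#' @param model A `gene_model`.
#' @param cdna,gdna The [seq_record]s the model was built from.
#' @return `TRUE` invisibly; otherwise an error describing the violated
#'   invariant.
#' @export
validate_gene_model <- function(model, cdna, gdna) {
  ex <- model$exons
  k <- nrow(ex)
  if (k == 0L) stop("gene model has no exons")
  if (any(ex[, "end"] <= ex[, "start"])) stop("empty exon interval")
  if (k > 1L && any(ex[-1L, "start"] < ex[-k, "end"])) stop("exons overlap or are unsorted")
  if (nrow(model$introns) != k - 1L) stop("intron count must be exon count - 1")
  g <- gdna$residues
  spliced <- paste(substring(g, ex[, "start"] + 1L, ex[, "end"]), collapse = "")
  if (model$mismatches == 0L && !identical(spliced, cdna$residues)) {
    stop("exon concatenation does not reproduce the cDNA")
  }
  if (nrow(model$introns)) {
    don <- substring(g, model$introns[, "start"] + 1L, model$introns[, "start"] + 2L)
    acc <- substring(g, model$introns[, "end"] - 1L, model$introns[, "end"])
    if (any(don != "GT") || any(acc != "AG")) stop("non-canonical intron boundary (GT..AG required)")
  }
  invisible(TRUE)
}

# Longest common extension of a[ai..] vs b[bi..] (raw vectors), allowing up
# to `budget` mismatches. Returns the extension lengths at which each
# mismatch occurs plus the maximal extension length.
extend_match <- function(a, b, ai, bi, budget = 0L) {
  len <- min(length(a) - ai + 1L, length(b) - bi + 1L)
  if (len <= 0L) return(list(max_len = 0L, mismatch_at = integer(0)))
  cmp <- a[ai:(ai + len - 1L)] != b[bi:(bi + len - 1L)]
  mm <- which(cmp)
  if (length(mm) <= budget) {
    list(max_len = len, mismatch_at = mm)
  } else {
    list(max_len = mm[[budget + 1L]] - 1L, mismatch_at = mm[seq_len(budget)])
  }
}

#' Spliced alignment of a cDNA onto a genomic allele
#'
#' Chains maximal exact anchors between the cDNA and the genomic sequence,
#' in order, allowing gaps in the genomic sequence (introns) only where the
#' gap starts with `GT` and ends with `AG`. Among all GT-AG-consistent
#' chains covering the full cDNA, the chain with the fewest introns is
#' chosen, ties broken by leftmost intron starts. The search is exhaustive
#' (memoised depth-first over cDNA/genomic offset pairs), which is
#' comfortable at single-gene scale (a few kb).
#'
#' @param cdna,gdna dna [seq_record]s; forward strand only.
#' @param min_exon Minimum exon length (nt) accepted at a splice, guarding
#'   against spurious micro-exons. Default 20.
#' @param max_mismatch_per_exon Per-exon substitution budget; the default 0
#'   demands an exact splice (appropriate when cDNA and gDNA come from the
#'   same allele). Mismatches are never allowed inside the `min_exon`-long
#'   anchor that re-seeds matching after an intron.
#' @return A `gene_model` (see [gene_model]). When no consistent chain
#'   exists an error of class `unannotatable_error` is signalled; its
#'   `partial` field carries the longest partial exon chain found.
#' @export
spliced_align <- function(cdna, gdna, min_exon = 20L, max_mismatch_per_exon = 0L) {
  stopifnot(inherits(cdna, "seq_record"), inherits(gdna, "seq_record"),
            cdna$moltype == "dna", gdna$moltype == "dna")
  cs <- cdna$residues
  gs <- gdna$residues
  nc <- nchar(cs)
  ng <- nchar(gs)
  cr <- charToRaw(cs)
  gr <- charToRaw(gs)
  budget <- as.integer(max_mismatch_per_exon)

  finish <- function(exons, mismatches) {
    model <- new_gene_model(gdna$seq_id, cdna$seq_id, exons, nc, find_orf(cdna), mismatches)
    validate_gene_model(model, cdna, gdna)
    model
  }

  # Fast path: the cDNA is an exact substring of the genomic sequence.
  hit <- regexpr(cs, gs, fixed = TRUE)
  if (hit[[1]] != -1L) {
    s0 <- as.integer(hit[[1]]) - 1L
    return(finish(cbind(s0, s0 + nc), 0L))
  }

  memo <- new.env(parent = emptyenv())
  states <- 0L
  partial <- list(ci = 0L, exons = NULL)

  # Candidate solutions are compared by (intron count, intron start vector,
  # exon1 start), all ascending.
  better <- function(x, y) {
    if (is.null(y)) return(TRUE)
    if (x$n_introns != y$n_introns) return(x$n_introns < y$n_introns)
    ix <- x$istarts; iy <- y$istarts
    for (i in seq_along(ix)) {
      if (ix[[i]] != iy[[i]]) return(ix[[i]] < iy[[i]])
    }
    FALSE
  }

  # Best suffix solution for "cDNA from ci must continue at genomic gi".
  solve <- function(ci, gi) {
    key <- paste(ci, gi)
    if (!is.null(res <- memo[[key]])) return(if (isFALSE(res)) NULL else res)
    states <<- states + 1L
    if (states > 50000L) {
      stop("spliced_align: search space too large; sequences may be too repetitive")
    }
    ext <- extend_match(cr, gr, ci, gi, budget)
    rem <- nc - ci + 1L
    best <- NULL
    if (ext$max_len >= rem) {
      mm_here <- sum(ext$mismatch_at <= rem)
      best <- list(
        n_introns = 0L, istarts = integer(0),
        exons = list(c(gi, gi + rem - 1L)), mismatches = mm_here
      )
    }
    if (ci + ext$max_len - 1L > partial$ci) {
      partial <<- list(ci = ci + ext$max_len - 1L,
                       exons = list(c(gi, gi + ext$max_len - 1L)))
    }
    k_max <- min(ext$max_len, rem - min_exon)
    if (k_max >= min_exon) {
      for (k in min_exon:k_max) {
        don <- gi + k                                   # 1-based intron start
        if (don + 3L > ng) next
        if (gs_char(gr, don) != "G" || gs_char(gr, don + 1L) != "T") next
        ci2 <- ci + k
        anchor <- substr(cs, ci2, ci2 + min_exon - 1L)
        occ <- find_occurrences(gs, anchor, don + 4L)
        for (p in occ) {
          if (substr(gs, p - 2L, p - 1L) != "AG") next
          sub <- solve(ci2, p)
          if (is.null(sub)) next
          cand <- list(
            n_introns = sub$n_introns + 1L,
            istarts = c(don, sub$istarts),
            exons = c(list(c(gi, gi + k - 1L)), sub$exons),
            mismatches = sum(ext$mismatch_at <= k) + sub$mismatches
          )
          if (better(cand, best)) best <- cand
        }
      }
    }
    memo[[key]] <- if (is.null(best)) FALSE else best
    best
  }

  # Exon-1 seeds: occurrences of the leading anchor in the genomic sequence.
  seed_len <- min(min_exon, nc)
  seeds <- find_occurrences(gs, substr(cs, 1L, seed_len), 1L)
  overall <- NULL
  for (s in seeds) {
    sol <- solve(1L, s)
    if (is.null(sol)) next
    if (better(sol, overall)) overall <- sol
  }
  if (is.null(overall)) {
    cond <- structure(
      class = c("unannotatable_error", "error", "condition"),
      list(
        message = sprintf(
          "no GT..AG-consistent exon chain covers cDNA %s on %s (longest partial chain reaches cDNA position %d)",
          cdna$seq_id, gdna$seq_id, partial$ci
        ),
        call = sys.call(-1),
        partial = partial
      )
    )
    stop(cond)
  }
  exons <- do.call(rbind, lapply(overall$exons, function(e) c(e[1] - 1L, e[2])))
  finish(exons, overall$mismatches)
}

gs_char <- function(raw, i) rawToChar(raw[i])

# All 1-based start positions >= from of `pattern` in `text` (fixed match).
find_occurrences <- function(text, pattern, from = 1L) {
  if (from > nchar(text)) return(integer(0))
  hits <- gregexpr(pattern, substr(text, from, nchar(text)), fixed = TRUE)[[1]]
  if (hits[[1]] == -1L) return(integer(0))
  as.integer(hits) + from - 1L
}

#' Extract intron sequences from an annotated allele
#'
#' @param model A `gene_model` for `gdna`.
#' @param gdna The genomic [seq_record].
#' @return A data.frame with one row per intron: `intron` (index from 1),
#'   `residues`, `length`.
#' @export
extract_introns <- function(model, gdna) {
  stopifnot(inherits(model, "gene_model"))
  iv <- model$introns
  if (nrow(iv) == 0L) {
    return(data.frame(intron = integer(0), residues = character(0), length = integer(0),
                      stringsAsFactors = FALSE))
  }
  res <- substring(gdna$residues, iv[, "start"] + 1L, iv[, "end"])
  data.frame(
    intron = seq_len(nrow(iv)),
    residues = res,
    length = iv[, "end"] - iv[, "start"],
    stringsAsFactors = FALSE
  )
}

#' cDNA intervals of the exons of a model
#'
#' @param model A `gene_model`.
#' @return Integer matrix (`start`, `end`), 0-based half-open on the cDNA,
#'   one row per exon.
#' @export
exon_cdna_intervals <- function(model) {
  widths <- model$exons[, "end"] - model$exons[, "start"]
  ends <- cumsum(widths)
  cbind(start = c(0L, ends[-length(ends)]), end = as.integer(ends))
}

#' Partition the coding sequence into analysis regions
#'
#' Two schemes are supported. `per_exon` reports every exon's cDNA
#' interval. `pbr_vs_rest` splits the ORF into the peptide-binding region
#' (PBR) -- operationally the union of exons 2 and 3, the exons encoding
#' the beta1/beta2 domains that contact presented peptides -- and the rest
#' of the ORF. The PBR interval is clipped to the ORF and expanded to whole
#' codons of the ORF frame (start rounded down, end rounded up), since the
#' downstream codon test consumes whole codons.
#'
#' @param model A `gene_model` whose cDNA has a located ORF.
#' @param scheme `"per_exon"` or `"pbr_vs_rest"`.
#' @return An object of class `region_partition`: a list with `intervals`
#'   (named list of 0-based half-open cDNA intervals) and `codons` (named
#'   list of 1-based sense-codon indices within the ORF; the terminal stop
#'   codon is never included).
#' @export
partition_regions <- function(model, scheme = c("pbr_vs_rest", "per_exon")) {
  scheme <- match.arg(scheme)
  ex <- exon_cdna_intervals(model)
  if (scheme == "per_exon") {
    intervals <- lapply(seq_len(nrow(ex)), function(i) ex[i, , drop = TRUE])
    names(intervals) <- paste0("exon", seq_len(nrow(ex)))
    return(structure(list(intervals = intervals, codons = NULL, scheme = scheme),
                     class = "region_partition"))
  }
  if (nrow(ex) < 3L) stop("pbr_vs_rest requires a model with at least 3 exons")
  orf <- model$orf
  if (!isTRUE(orf$found)) stop("pbr_vs_rest requires a located ORF on the cDNA")
  orf_len <- orf$end - orf$start
  n_codons <- orf_len %/% 3L          # includes the terminal stop codon
  n_sense <- n_codons - 1L
  pbr_raw <- c(ex[2L, "start"], ex[3L, "end"])
  # clip to ORF, then round outward to codon boundaries of the ORF frame
  s <- max(pbr_raw[[1]], orf$start)
  e <- min(pbr_raw[[2]], orf$end)
  if (e <= s) stop("exons 2-3 do not overlap the ORF")
  cod_s <- (s - orf$start) %/% 3L               # 0-based codon index
  cod_e <- ((e - orf$start) + 2L) %/% 3L        # exclusive
  cod_e <- min(cod_e, n_codons)
  pbr_codons <- seq.int(cod_s + 1L, cod_e)
  pbr_codons <- pbr_codons[pbr_codons <= n_sense]
  rest_codons <- setdiff(seq_len(n_sense), pbr_codons)
  pbr_iv <- c(start = orf$start + cod_s * 3L, end = orf$start + cod_e * 3L)
  flanks <- rbind(
    c(start = orf$start, end = pbr_iv[["start"]]),
    c(start = pbr_iv[["end"]], end = orf$end)
  )
  flanks <- flanks[flanks[, "end"] > flanks[, "start"], , drop = FALSE]
  intervals <- list(PBR = rbind(pbr_iv, deparse.level = 0), nonPBR = flanks)
  structure(
    list(
      intervals = intervals,
      codons = list(PBR = pbr_codons, nonPBR = rest_codons),
      scheme = scheme,
      n_sense_codons = n_sense
    ),
    class = "region_partition"
  )
}

#' Map a cDNA interval onto genomic coordinates through a gene model
#'
#' @param model A `gene_model`.
#' @param interval Length-2 integer vector, 0-based half-open on the cDNA.
#' @return Integer matrix of genomic intervals (0-based half-open), one row
#'   per exon piece.
#' @export
map_cdna_to_genomic <- function(model, interval) {
  ex_c <- exon_cdna_intervals(model)
  ex_g <- model$exons
  out <- list()
  for (i in seq_len(nrow(ex_c))) {
    s <- max(interval[[1]], ex_c[i, "start"])
    e <- min(interval[[2]], ex_c[i, "end"])
    if (e > s) {
      off <- ex_g[i, "start"] - ex_c[i, "start"]
      out[[length(out) + 1L]] <- c(s + off, e + off)
    }
  }
  if (!length(out)) return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  m <- do.call(rbind, out)
  dimnames(m) <- list(NULL, c("start", "end"))
  m
}

#' Export a gene model as GFF3
#'
#' Writes gene, exon and CDS features (1-based inclusive, per the GFF3
#' standard) via `rtracklayer`.
#'
#' @param model A `gene_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_gff3 <- function(model, path) {
  ex <- model$exons
  gene_id <- paste0("gene:", model$genomic_id)
  feats <- data.frame(
    start = ex[, "start"] + 1L, end = ex[, "end"],
    type = "exon",
    ID = paste0(model$genomic_id, ".exon", seq_len(nrow(ex))),
    Parent = gene_id,
    phase = NA_integer_,
    stringsAsFactors = FALSE
  )
  if (isTRUE(model$orf$found)) {
    cds <- map_cdna_to_genomic(model, c(model$orf$start, model$orf$end))
    widths <- cds[, "end"] - cds[, "start"]
    preceding <- cumsum(c(0L, widths[-length(widths)]))
    feats <- rbind(feats, data.frame(
      start = cds[, "start"] + 1L, end = cds[, "end"],
      type = "CDS",
      ID = paste0(model$genomic_id, ".cds", seq_len(nrow(cds))),
      Parent = gene_id,
      phase = (3L - preceding %% 3L) %% 3L,
      stringsAsFactors = FALSE
    ))
  }
  feats <- rbind(data.frame(
    start = min(ex[, "start"]) + 1L, end = max(ex[, "end"]),
    type = "gene", ID = gene_id, Parent = NA_character_, phase = NA_integer_,
    stringsAsFactors = FALSE
  ), feats)
  gr <- GenomicRanges::GRanges(
    seqnames = model$genomic_id,
    ranges = IRanges::IRanges(start = feats$start, end = feats$end),
    strand = "+",
    type = feats$type,
    ID = feats$ID,
    Parent = feats$Parent,
    phase = feats$phase
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Export a gene model as JSON
#'
#' @param model A `gene_model`.
#' @param path Output path; when `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string when `path` is `NULL`.
#' @export
export_gene_model_json <- function(model, path = NULL) {
  doc <- list(
    genomic_id = model$genomic_id,
    cdna_id = model$cdna_id,
    exons = unname(apply(model$exons, 1L, function(r) list(start = r[[1]], end = r[[2]]))),
    introns = unname(apply(model$introns, 1L, function(r) list(start = r[[1]], end = r[[2]]))),
    cdna_len = model$cdna_len,
    utr5_len = model$utr5_len,
    utr3_len = model$utr3_len,
    orf = if (isTRUE(model$orf$found)) {
      list(start = model$orf$start, end = model$orf$end, protein = model$orf$protein)
    } else NULL,
    mismatches = model$mismatches
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(path)
}
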