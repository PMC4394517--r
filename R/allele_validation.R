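#' Collapse clone-level sequences into validated alleles
#'
#' Bacterial cloning of PCR products yields many sequenced clones per
#' individual, a mixture of true allele sequences and PCR/sequencing
#' artifacts. The clone-support rule accepts a sequence as a real allele
#' only when it was observed, identically, in at least `min_support` clones
#' of at least one individual; sequences seen in only one or two clones are
#' discarded as likely artifacts. Clones are compared by exact string
#' identity after uppercasing -- no error-tolerant clustering -- and any
#' validated allele containing an `N` base is rejected, since downstream
#' analyses collapse alleles by exact identity.
#'
#' Support is counted per individual; an allele retained because one
#' individual supports it at `>= min_support` lists as carriers every
#' individual contributing at least one clone of it.
#'
#' @param clones Data.frame with character columns `clone_id`,
#'   `individual_id`, `source` (`"cdna"`/`"gdna"`) and `residues`.
#' @param min_support Minimum clone count within a single individual for a
#'   sequence to be validated (default 3, i.e. "more than two clones").
#' @param prefix Nomenclature prefix for allele names; alleles are numbered
#'   `<prefix>*01`, `<prefix>*02`, ... in descending order of total
#'   support, ties broken by sequence lexicographic order. When clones of
#'   both template sources are present, names carry a `-c`/`-g` source
#'   suffix so cDNA- and gDNA-derived alleles stay distinguishable.
#' @return A list of class `allele_set`:
#'   * `alleles`: data.frame `allele_name`, `residues`, `source`,
#'     `support` (total clones), `carriers` (comma-separated individuals);
#'   * `genotypes`: data.frame `individual_id`, `allele_name`, `source`
#'     (the genotype table, one row per carried allele);
#'   * `discards`: data.frame of excluded sequences with their clone
#'     counts and the reason for exclusion.
#'
#'   If every clone is discarded the allele table is empty and the discard
#'   report is complete; a warning, not an error.
#' @export
collapse_clones <- function(clones, min_support = 3L, prefix = "Allele") {
  stopifnot(is.data.frame(clones), nrow(clones) > 0L, min_support >= 1L)
  required <- c("clone_id", "individual_id", "source", "residues")
  missing <- setdiff(required, names(clones))
  if (length(missing)) stop("clones is missing column(s): ", paste(missing, collapse = ", "))
  clones$residues <- toupper(clones$residues)
  bad <- grepl("[^ACGTN]", clones$residues)
  if (any(bad)) {
    stop("clone(s) with invalid dna residues: ",
         paste(utils::head(clones$clone_id[bad], 5L), collapse = ", "))
  }
  multi_source <- length(unique(clones$source)) > 1L

  out_alleles <- list()
  out_geno <- list()
  out_disc <- list()
  for (src in sort(unique(clones$source))) {
    sub <- clones[clones$source == src, , drop = FALSE]
    # per-sequence, per-individual clone counts
    counts <- stats::aggregate(
      list(n = sub$clone_id),
      by = list(residues = sub$residues, individual_id = sub$individual_id),
      FUN = length
    )
    per_seq_max <- tapply(counts$n, counts$residues, max)
    per_seq_tot <- tapply(counts$n, counts$residues, sum)
    seqs <- names(per_seq_max)
    has_n <- grepl("N", seqs, fixed = TRUE)
    validated <- per_seq_max >= min_support & !has_n

    disc <- seqs[!validated]
    if (length(disc)) {
      reason <- ifelse(
        has_n[!validated], "contains N",
        ifelse(per_seq_tot[disc] >= min_support,
               sprintf("max per-individual support %d < %d (total %d across individuals)",
                       per_seq_max[disc], min_support, per_seq_tot[disc]),
               "insufficient clone support")
      )
      out_disc[[src]] <- data.frame(
        residues = disc,
        source = src,
        total_clones = as.integer(per_seq_tot[disc]),
        max_support_one_individual = as.integer(per_seq_max[disc]),
        reason = reason,
        stringsAsFactors = FALSE
      )
    }
    keep <- seqs[validated]
    if (!length(keep)) next
    tot <- as.integer(per_seq_tot[keep])
    ord <- order(-tot, keep)
    keep <- keep[ord]
    tot <- tot[ord]
    suffix <- if (multi_source) c(cdna = "-c", gdna = "-g")[[src]] else ""
    nm <- sprintf("%s*%02d%s", prefix, seq_along(keep), suffix)
    carriers <- lapply(keep, function(s) {
      sort(unique(counts$individual_id[counts$residues == s & counts$n >= 1L]))
    })
    out_alleles[[src]] <- data.frame(
      allele_name = nm,
      residues = keep,
      source = src,
      support = tot,
      carriers = vapply(carriers, paste, character(1), collapse = ","),
      stringsAsFactors = FALSE
    )
    out_geno[[src]] <- data.frame(
      individual_id = unlist(carriers),
      allele_name = rep(nm, lengths(carriers)),
      source = src,
      stringsAsFactors = FALSE
    )
  }
  alleles <- if (length(out_alleles)) do.call(rbind, out_alleles) else {
    data.frame(allele_name = character(0), residues = character(0), source = character(0),
               support = integer(0), carriers = character(0), stringsAsFactors = FALSE)
  }
  genotypes <- if (length(out_geno)) do.call(rbind, out_geno) else {
    data.frame(individual_id = character(0), allele_name = character(0), source = character(0),
               stringsAsFactors = FALSE)
  }
  discards <- if (length(out_disc)) do.call(rbind, out_disc) else {
    data.frame(residues = character(0), source = character(0), total_clones = integer(0),
               max_support_one_individual = integer(0), reason = character(0),
               stringsAsFactors = FALSE)
  }
  rownames(alleles) <- rownames(genotypes) <- rownames(discards) <- NULL
  if (nrow(alleles) == 0L) {
    warning("no sequence met the clone-support rule; all clones discarded")
  }
  structure(
    list(alleles = alleles, genotypes = genotypes, discards = discards,
         min_support = as.integer(min_support)),
    class = "allele_set"
  )
}

#' @export
print.allele_set <- function(x, ...) {
  cat(sprintf(
    "<allele_set> %d validated allele(s) from %d individual(s); %d sequence(s) discarded (min_support = %d)\n",
    nrow(x$alleles), length(unique(x$genotypes$individual_id)), nrow(x$discards), x$min_support
  ))
  invisible(x)
}

#' Per-individual allele counts from a genotype table
#'
#' @param genotypes Data.frame with columns `individual_id`, `allele_name`.
#' @return Named integer vector of distinct-allele counts per individual.
#' @export
allele_counts <- function(genotypes) {
  if (nrow(genotypes) == 0L) return(stats::setNames(integer(0), character(0)))
  tab <- tapply(genotypes$allele_name, genotypes$individual_id,
                function(a) length(unique(a)))
  stats::setNames(as.integer(tab), names(tab))
}

#' Individuals-by-alleles incidence matrix
#'
#' Binary matrix whose `[i, a]` entry is 1 when individual `i` carries
#' allele `a`; row sums equal the per-individual allele counts.
#'
#' @param genotypes Data.frame with columns `individual_id`, `allele_name`.
#' @return Integer matrix, individuals in rows (sorted), alleles in
#'   columns (sorted).
#' @export
allele_sharing_matrix <- function(genotypes) {
  inds <- sort(unique(genotypes$individual_id))
  alls <- sort(unique(genotypes$allele_name))
  m <- matrix(0L, nrow = length(inds), ncol = length(alls),
              dimnames = list(inds, alls))
  if (nrow(genotypes)) {
    m[cbind(match(genotypes$individual_id, inds), match(genotypes$allele_name, alls))] <- 1L
  }
  m
}

#' Write the outputs of allele validation
#'
#' Emits the validated alleles as FASTA (allele names as headers, carriers
#' in the description), the genotype table and the discard report as TSV.
#'
#' @param aset An `allele_set` from [collapse_clones()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_allele_set <- function(aset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "alleles.fasta")
  records <- lapply(seq_len(nrow(aset$alleles)), function(i) {
    a <- aset$alleles[i, ]
    seq_record(a$allele_name, a$residues,
               description = sprintf("support=%d carriers=%s source=%s",
                                     a$support, a$carriers, a$source))
  })
  if (length(records)) write_fasta(records, fa) else file.create(fa)
  geno <- file.path(dir, "genotypes.tsv")
  utils::write.table(aset$genotypes, geno, sep = "\t", quote = FALSE, row.names = FALSE)
  disc <- file.path(dir, "discards.tsv")
  utils::write.table(aset$discards, disc, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(alleles = fa, genotypes = geno, discards = disc))
}
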