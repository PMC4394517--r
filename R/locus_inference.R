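#' Pairwise p-distance matrix between alleles
#'
#' Distance = mismatched columns / compared columns, where columns
#' containing an alignment gap are excluded. Equal-length inputs are
#' compared positionally; unequal-length inputs are aligned pairwise with
#' the [build_msa()] scoring scheme. When mixing whole-length and partial
#' alleles it is usually preferable to pass the intersected annotated
#' region (e.g. the concatenated exon sequence spanning exons 1-4) via
#' `region`, a 0-based half-open interval applied to every sequence.
#'
#' @param seqs Named character vector, list of dna [seq_record]s, or the
#'   `alleles` data.frame of an `allele_set`; at least 2 sequences.
#' @param region Optional length-2 interval restricting the comparison
#'   (equal-length inputs only).
#' @return Symmetric numeric matrix with zero diagonal, labelled by
#'   sequence name.
#' @export
p_distance_matrix <- function(seqs, region = NULL) {
  strings <- if (is.data.frame(seqs)) {
    stats::setNames(seqs$residues, seqs$allele_name)
  } else {
    as_seq_strings(seqs)
  }
  n <- length(strings)
  if (n < 2L) stop("p_distance_matrix requires at least 2 sequences")
  ids <- names(strings)
  if (!is.null(region)) {
    stopifnot(length(unique(nchar(strings))) == 1L)
    strings <- substr(strings, region[[1]] + 1L, region[[2]])
  }
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  equal_len <- length(unique(nchar(strings))) == 1L
  chars <- if (equal_len) lapply(strings, charToRaw) else NULL
  mat <- if (!equal_len) {
    Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                             baseOnly = FALSE, type = "DNA")
  } else NULL
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (equal_len) {
        d[i, j] <- d[j, i] <- mean(chars[[i]] != chars[[j]])
      } else {
        pa <- Biostrings::pairwiseAlignment(
          pattern = strings[[i]], subject = strings[[j]], type = "global",
          substitutionMatrix = mat, gapOpening = 5, gapExtension = 1
        )
        qa <- charToRaw(as.character(Biostrings::alignedPattern(pa)))
        sa <- charToRaw(as.character(Biostrings::alignedSubject(pa)))
        gap <- charToRaw("-")
        keep <- qa != gap & sa != gap
        d[i, j] <- d[j, i] <- mean(qa[keep] != sa[keep])
      }
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining via [ape::nj()]. Negative branch lengths are
#' clamped to zero and the number of clamped branches reported.
#'
#' @param dm Symmetric distance matrix with at least 3 labels.
#' @return List of class `nj_result`: `tree` (an `ape` phylo object),
#'   `newick` (newick text) and `n_clamped`.
#' @export
nj_tree <- function(dm) {
  if (nrow(dm) < 3L) stop("nj_tree requires at least 3 labels")
  tree <- ape::nj(stats::as.dist(dm))
  neg <- tree$edge.length < 0
  tree$edge.length[neg] <- 0
  structure(
    list(tree = tree, newick = ape::write.tree(tree), n_clamped = sum(neg)),
    class = "nj_result"
  )
}

#' @export
print.nj_result <- function(x, ...) {
  cat(sprintf("<nj_result> %d tips%s\n", length(x$tree$tip.label),
              if (x$n_clamped) sprintf(" (%d negative branch(es) clamped to 0)", x$n_clamped) else ""))
  cat(" ", x$newick, "\n")
  invisible(x)
}

#' Diploid lower bound on the locus number
#'
#' A diploid individual carries at most two alleles per locus, so an
#' individual with k distinct validated alleles implies at least
#' ceiling(k / 2) loci.
#'
#' @param genotypes Genotype table (`individual_id`, `allele_name`) or a
#'   named integer vector of per-individual allele counts.
#' @return Integer lower bound.
#' @export
min_locus_bound <- function(genotypes) {
  counts <- if (is.data.frame(genotypes)) allele_counts(genotypes) else genotypes
  if (length(counts) == 0L) stop("min_locus_bound: empty genotype table")
  as.integer(ceiling(max(counts) / 2))
}

carrier_incidence <- function(labels, genotypes) {
  inds <- sort(unique(genotypes$individual_id))
  m <- matrix(0L, nrow = length(labels), ncol = length(inds),
              dimnames = list(labels, inds))
  hit <- genotypes$allele_name %in% labels
  m[cbind(match(genotypes$allele_name[hit], labels),
          match(genotypes$individual_id[hit], inds))] <- 1L
  m
}

#' Partition alleles into candidate locus groups under the diploid
#' constraint
#'
#' Groups alleles by sequence similarity such that no group ever contains
#' more than two alleles of any one individual -- the defining property of
#' a single locus in a diploid. The constraint is a hard merge blocker:
#' average-linkage agglomeration proceeds from singletons, always taking
#' the legal merge with the smallest average distance (ties broken by the
#' lexicographically smallest label pair), and stops only when no legal
#' merge remains. For small allele sets (`n <= exhaustive_limit`) the
#' greedy result is replaced by an exhaustive search over all
#' diploid-legal set partitions, which guarantees the minimal number of
#' groups (among minimal partitions the one with the smallest total
#' within-group mean distance is chosen); greedy agglomeration can stall
#' above the true minimum on adversarial carrier patterns, and the
#' exhaustive search is cheap at these sizes.
#'
#' After grouping, singleton groups whose nearest-neighbor distance
#' exceeds the `outlier_quantile` quantile of all pairwise distances are
#' moved to `unassigned` (alleles lacking any close relative do not
#' support a locus assignment). The reported estimate is
#' `max(number of groups containing at least one allele of the most
#' allele-rich individual, min_locus_bound)` and is a lower bound: two
#' groups may always come from closely related loci that no amount of
#' clustering can tell apart.
#'
#' @param dm Distance matrix from [p_distance_matrix()].
#' @param genotypes Genotype table covering every allele in `dm`.
#' @param outlier_quantile Quantile of all pairwise distances above which
#'   an isolated singleton is left unassigned (default 0.90).
#' @param exhaustive_limit Maximum allele count for the exact partition
#'   search (default 10).
#' @return List of class `locus_grouping`: `groups` (list of allele-name
#'   vectors), `unassigned`, `per_group_counts` (groups x individuals
#'   matrix), `min_locus_estimate`, `bound`, `method`.
#' @export
constrained_grouping <- function(dm, genotypes, outlier_quantile = 0.90,
                                 exhaustive_limit = 10L) {
  labels <- rownames(dm)
  stopifnot(!is.null(labels), all(labels == colnames(dm)))
  missing <- setdiff(labels, genotypes$allele_name)
  if (length(missing)) {
    stop("alleles absent from the genotype table: ", paste(missing, collapse = ", "))
  }
  n <- length(labels)
  inc <- carrier_incidence(labels, genotypes)
  groups <- if (n <= exhaustive_limit) {
    exact_min_partition(dm, inc)
  } else {
    greedy_agglomeration(dm, inc, labels)
  }
  method <- if (n <= exhaustive_limit) "exhaustive" else "agglomerative"

  # outlier rule: isolated singletons carry no grouping information
  unassigned <- character(0)
  if (n >= 2L) {
    off <- dm[upper.tri(dm)]
    cutoff <- stats::quantile(off, outlier_quantile, names = FALSE)
    singleton <- vapply(groups, length, integer(1)) == 1L
    for (gi in which(singleton)) {
      lab <- groups[[gi]]
      nn <- min(dm[lab, setdiff(labels, lab)])
      if (nn > cutoff) unassigned <- c(unassigned, lab)
    }
    if (length(unassigned)) {
      groups <- groups[!vapply(groups, function(g) all(g %in% unassigned), logical(1))]
    }
  }
  # deterministic presentation: groups ordered by their smallest label
  groups <- lapply(groups, sort)
  groups <- groups[order(vapply(groups, `[[`, character(1), 1L))]

  counts <- matrix(0L, nrow = length(groups), ncol = ncol(inc),
                   dimnames = list(if (length(groups)) paste0("group", seq_along(groups)),
                                   colnames(inc)))
  for (gi in seq_along(groups)) {
    counts[gi, ] <- colSums(inc[groups[[gi]], , drop = FALSE])
  }
  stopifnot(all(counts <= 2L))
  totals <- allele_counts(genotypes)
  bound <- min_locus_bound(totals)
  richest <- names(totals)[totals == max(totals)]
  spanned <- if (length(groups)) {
    max(vapply(richest, function(ind) as.numeric(sum(counts[, ind] > 0)), numeric(1)))
  } else 0
  structure(
    list(
      groups = groups, unassigned = unassigned,
      per_group_counts = counts,
      min_locus_estimate = as.integer(max(spanned, bound)),
      bound = bound, method = method
    ),
    class = "locus_grouping"
  )
}

#' @export
print.locus_grouping <- function(x, ...) {
  cat(sprintf(
    "<locus_grouping> %d group(s), %d unassigned; minimum locus estimate %d (diploid bound %d, %s)\n",
    length(x$groups), length(x$unassigned), x$min_locus_estimate, x$bound, x$method
  ))
  for (i in seq_along(x$groups)) {
    cat(sprintf("  group %d: %s\n", i, paste(x$groups[[i]], collapse = ", ")))
  }
  if (length(x$unassigned)) cat("  unassigned:", paste(x$unassigned, collapse = ", "), "\n")
  invisible(x)
}

# Greedy constrained average-linkage agglomeration. `inc` is the
# allele x individual incidence matrix.
greedy_agglomeration <- function(dm, inc, labels) {
  groups <- as.list(labels)
  counts <- lapply(seq_along(labels), function(i) inc[i, ])
  repeat {
    k <- length(groups)
    if (k < 2L) break
    best <- NULL
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        if (any(counts[[i]] + counts[[j]] > 2L)) next
        avg <- mean(dm[groups[[i]], groups[[j]]])
        rep_pair <- sort(c(min(groups[[i]]), min(groups[[j]])))
        if (is.null(best) || avg < best$avg ||
            (avg == best$avg && (rep_pair[[1]] < best$rep[[1]] ||
                                 (rep_pair[[1]] == best$rep[[1]] && rep_pair[[2]] < best$rep[[2]])))) {
          best <- list(i = i, j = j, avg = avg, rep = rep_pair)
        }
      }
    }
    if (is.null(best)) break
    groups[[best$i]] <- c(groups[[best$i]], groups[[best$j]])
    counts[[best$i]] <- counts[[best$i]] + counts[[best$j]]
    groups[[best$j]] <- NULL
    counts[[best$j]] <- NULL
  }
  groups
}

# Exhaustive search over diploid-legal set partitions: minimal group
# count, ties broken by the smallest total within-group mean distance,
# then by enumeration order (deterministic).
exact_min_partition <- function(dm, inc) {
  labels <- rownames(dm)
  n <- length(labels)
  best <- NULL
  blocks <- list()        # list of integer index vectors
  block_counts <- list()  # per-block individual counts
  score <- function(blks) {
    sum(vapply(blks, function(b) {
      if (length(b) < 2L) return(0)
      mean(dm[b, b][upper.tri(matrix(0, length(b), length(b)))])
    }, numeric(1)))
  }
  recurse <- function(i) {
    if (!is.null(best) && length(blocks) > best$k) return()
    if (i > n) {
      k <- length(blocks)
      sc <- score(blocks)
      if (is.null(best) || k < best$k || (k == best$k && sc < best$score)) {
        best <<- list(k = k, score = sc, blocks = blocks)
      }
      return()
    }
    for (b in seq_along(blocks)) {
      if (any(block_counts[[b]] + inc[i, ] > 2L)) next
      blocks[[b]] <<- c(blocks[[b]], i)
      block_counts[[b]] <<- block_counts[[b]] + inc[i, ]
      recurse(i + 1L)
      blocks[[b]] <<- blocks[[b]][-length(blocks[[b]])]
      block_counts[[b]] <<- block_counts[[b]] - inc[i, ]
    }
    blocks[[length(blocks) + 1L]] <<- i
    block_counts[[length(block_counts) + 1L]] <<- inc[i, ]
    recurse(i + 1L)
    blocks[[length(blocks)]] <<- NULL
    block_counts[[length(block_counts)]] <<- NULL
  }
  recurse(1L)
  lapply(best$blocks, function(b) labels[b])
}

#' Export alleles and an analysis stub as NEXUS
#'
#' Writes the allele sequences as a NEXUS data block followed by a MrBayes
#' command block (GTR substitution model with gamma-distributed rate
#' variation) so the grouping can be reproduced against an externally
#' estimated Bayesian tree.
#'
#' @param seqs Named character vector or list of dna [seq_record]s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_nexus <- function(seqs, path) {
  strings <- as_seq_strings(seqs)
  ape::write.nexus.data(strsplit(strings, ""), file = path, interleaved = FALSE)
  block <- c(
    "begin mrbayes;",
    "  lset nst=6 rates=gamma;",
    "  [ mcmc ngen=1000000 samplefreq=100; sumt burnin=2500; ]",
    "end;"
  )
  cat(block, file = path, sep = "\n", append = TRUE)
  invisible(path)
}

#' Write a locus grouping report as JSON
#'
#' @param grouping A `locus_grouping`.
#' @param path Output path; when `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
write_grouping_json <- function(grouping, path = NULL) {
  doc <- list(
    groups = grouping$groups,
    unassigned = grouping$unassigned,
    per_individual_counts = as.data.frame(grouping$per_group_counts),
    min_locus_estimate = grouping$min_locus_estimate,
    diploid_bound = grouping$bound,
    method = grouping$method,
    note = "minimum estimate: closely related loci cannot be excluded"
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(path)
}
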