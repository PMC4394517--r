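#' Configuration for the multi-locus diploid simulator
#'
#' The generator emulates the data-generating process of a cloning study
#' of a multi-copy MHC-like gene: several loci sharing a 6-exon/5-intron
#' architecture, per-locus intron lengths driven by tandem-repeat copy
#' number, elevated nonsynonymous substitution in the peptide-binding
#' region (exons 2-3), diploid individuals drawing at most two alleles per
#' locus (and sometimes missing a locus entirely), and clone resampling
#' with per-base sequencing error.
#'
#' Defaults mirror the motivating study's conditions: a cDNA of 25 nt
#' 5'UTR + 747 nt ORF + 22 nt 3'UTR across six exons, intron 2 carrying a
#' GT microsatellite, intron 3 the GTCCAGTTGA decamer, intron 4 the
#' ACCTGTCTGTCTGCTC 16-mer, 4 loci in 8 diploid individuals, and 8-20
#' clones sequenced per template.
#'
#' @param n_loci Number of loci.
#' @param n_individuals Number of diploid individuals.
#' @param alleles_per_locus Size of the allele pool at each locus.
#' @param exon_lengths Exon lengths on the cDNA (nt); the first exon
#'   contains the 5'UTR and the last the 3'UTR.
#' @param utr5_len,utr3_len UTR lengths (nt) inside the terminal exons.
#' @param intron_base_lengths Intron scaffold lengths (nt) excluding the
#'   planted repeat block.
#' @param intron_repeat_units Per-intron repeat motif (`NA` for none).
#' @param intron_copy_range Per-intron two-column matrix (min, max) of
#'   repeat copy numbers drawn per locus.
#' @param locus_divergence Per-site substitution rate separating each
#'   locus founder from the shared root (exons; loci are well separated at
#'   the default 5%).
#' @param allele_divergence Per-site substitution rate separating alleles
#'   within a locus from their founder (default 0.5%).
#' @param pbr_multiplier Mutation-intensity multiplier for exons 2-3; the
#'   same factor biases acceptance toward nonsynonymous changes there, so
#'   a multiplier > 1 produces dN > dS in the PBR (1 = neutral).
#' @param intron_divergence Per-site substitution rate on intron scaffolds
#'   between alleles of a locus.
#' @param clone_depth Length-2 range of clones sequenced per carried
#'   allele.
#' @param error_rate Per-base substitution error rate of a clone
#'   (default 0.1%).
#' @param missing_prob Probability that an individual does not carry (or
#'   does not yield) a given locus.
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the configuration including the seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_loci = 4L,
                       n_individuals = 8L,
                       alleles_per_locus = 6L,
                       exon_lengths = c(79L, 270L, 282L, 90L, 33L, 40L),
                       utr5_len = 25L,
                       utr3_len = 22L,
                       intron_base_lengths = c(150L, 120L, 90L, 60L, 100L),
                       intron_repeat_units = c(NA, "GT", "GTCCAGTTGA", "ACCTGTCTGTCTGCTC", NA),
                       intron_copy_range = rbind(c(0, 0), c(8, 25), c(2, 18), c(1, 6), c(0, 0)),
                       locus_divergence = 0.05,
                       allele_divergence = 0.005,
                       pbr_multiplier = 5,
                       intron_divergence = 0.01,
                       clone_depth = c(8L, 20L),
                       error_rate = 0.001,
                       missing_prob = 0.1,
                       seed = 1L) {
  cfg <- list(
    n_loci = as.integer(n_loci), n_individuals = as.integer(n_individuals),
    alleles_per_locus = as.integer(alleles_per_locus),
    exon_lengths = as.integer(exon_lengths),
    utr5_len = as.integer(utr5_len), utr3_len = as.integer(utr3_len),
    intron_base_lengths = as.integer(intron_base_lengths),
    intron_repeat_units = as.character(intron_repeat_units),
    intron_copy_range = intron_copy_range,
    locus_divergence = locus_divergence, allele_divergence = allele_divergence,
    pbr_multiplier = pbr_multiplier, intron_divergence = intron_divergence,
    clone_depth = as.integer(clone_depth), error_rate = error_rate,
    missing_prob = missing_prob, seed = as.integer(seed)
  )
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(cfg$n_loci >= 1L, "n_loci must be positive")
  chk(cfg$n_individuals >= 1L, "n_individuals must be positive")
  chk(cfg$alleles_per_locus >= 1L, "alleles_per_locus must be positive")
  chk(length(cfg$exon_lengths) >= 2L && all(cfg$exon_lengths > 0L),
      "exon_lengths must be >= 2 positive lengths")
  chk(length(cfg$intron_base_lengths) == length(cfg$exon_lengths) - 1L,
      "need exactly one intron between consecutive exons")
  chk(length(cfg$intron_repeat_units) == length(cfg$intron_base_lengths),
      "intron_repeat_units must match intron count")
  chk(nrow(cfg$intron_copy_range) == length(cfg$intron_base_lengths),
      "intron_copy_range must have one row per intron")
  orf_len <- sum(cfg$exon_lengths) - cfg$utr5_len - cfg$utr3_len
  chk(orf_len > 6L && orf_len %% 3L == 0L,
      "exon lengths minus UTRs must leave an ORF of positive length divisible by 3")
  chk(cfg$utr5_len < cfg$exon_lengths[[1]], "5'UTR must fit in exon 1")
  chk(cfg$utr3_len < cfg$exon_lengths[[length(cfg$exon_lengths)]], "3'UTR must fit in the last exon")
  for (r in c("locus_divergence", "allele_divergence", "intron_divergence",
              "error_rate", "missing_prob")) {
    chk(cfg[[r]] >= 0 && cfg[[r]] <= 1, paste(r, "must be in [0, 1]"))
  }
  chk(cfg$pbr_multiplier >= 1, "pbr_multiplier must be >= 1")
  chk(length(cfg$clone_depth) == 2L && all(cfg$clone_depth >= 1L) &&
        cfg$clone_depth[[1]] <= cfg$clone_depth[[2]],
      "clone_depth must be an increasing positive range")
  chk(all(cfg$intron_base_lengths >= 6L), "intron scaffolds must be at least 6 nt (GT..AG plus body)")
  if (length(problems)) {
    stop("invalid sim_config:\n  - ", paste(problems, collapse = "\n  - "))
  }
  structure(cfg, class = "sim_config")
}

random_bases <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# Random UTR without an ATG (an upstream in-frame ATG could lengthen the
# apparent ORF and shift the annotated UTRs).
random_utr <- function(n) {
  if (n == 0L) return("")
  s <- random_bases(n)
  gsub("ATG", "ACG", s, fixed = TRUE)
}

random_orf <- function(n_codons) {
  sense <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)
  body <- sample(sense[-match("ATG", sense)], n_codons - 2L, replace = TRUE)
  paste(c("ATG", body, sample(STOP_CODONS, 1L)), collapse = "")
}

# Codon-aware point mutagenesis of the ORF portion of a cDNA. Candidate
# positions are drawn with weight `multiplier` inside the PBR (mutation
# pressure concentrates on peptide-binding codons); a candidate is
# rejected when it creates or destroys a stop codon, and synonymous PBR
# candidates are accepted with probability 1/multiplier, biasing fixed
# PBR changes toward nonsynonymous ones.
mutate_orf <- function(cdna, orf_start, orf_len, n_mut, pbr_codons, multiplier) {
  if (n_mut <= 0L) return(cdna)
  x <- strsplit(cdna, "")[[1]]
  candidates <- (3L + 1L):(orf_len - 3L)     # never the initiator ATG or the stop
  cand_codon <- (candidates - 1L) %/% 3L + 1L
  weights <- ifelse(cand_codon %in% pbr_codons, multiplier, 1)
  placed <- 0L
  guard <- 0L
  while (placed < n_mut && guard < 50L * n_mut + 200L) {
    guard <- guard + 1L
    pos <- sample(candidates, 1L, prob = weights)
    cod_i <- (pos - 1L) %/% 3L + 1L
    abs_pos <- orf_start + pos                # 1-based on cDNA
    old <- x[[abs_pos]]
    new <- sample(setdiff(BASES, old), 1L)
    cs <- orf_start + (cod_i - 1L) * 3L + 1L
    codon_old <- paste(x[cs:(cs + 2L)], collapse = "")
    x[[abs_pos]] <- new
    codon_new <- paste(x[cs:(cs + 2L)], collapse = "")
    if (codon_new %in% STOP_CODONS || codon_old %in% STOP_CODONS) {
      x[[abs_pos]] <- old
      next
    }
    syn <- translate_codons(codon_old) == translate_codons(codon_new)
    in_pbr <- cod_i %in% pbr_codons
    if (in_pbr && syn && multiplier > 1 && stats::runif(1) > 1 / multiplier) {
      x[[abs_pos]] <- old
      next
    }
    placed <- placed + 1L
  }
  paste(x, collapse = "")
}

RAW_BASES <- charToRaw("ACGT")

mutate_neutral <- function(seq, rate) {
  n <- nchar(seq)
  k <- stats::rbinom(1L, n, rate)
  if (k == 0L) return(seq)
  r <- charToRaw(seq)
  pos <- sample.int(n, k)
  for (p in pos) {
    alt <- RAW_BASES[RAW_BASES != r[[p]]]
    r[[p]] <- alt[[sample.int(3L, 1L)]]
  }
  rawToChar(r)
}

# Intron = GT + left scaffold + repeat block + right scaffold + AG.
build_intron <- function(base_len, unit, copies) {
  body_len <- base_len - 4L
  left <- body_len %/% 2L
  right <- body_len - left
  rep_block <- if (!is.na(unit) && copies > 0) {
    strrep(unit, copies)
  } else ""
  paste0("GT", random_bases(left), rep_block, random_bases(right), "AG")
}

#' Simulate a ground-truthed multi-locus diploid cloning dataset
#'
#' See [sim_config()] for the generative model. Given the same
#' configuration (including seed), two runs produce byte-identical
#' outputs.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_result`:
#' * `clones`: data.frame `clone_id`, `individual_id`, `source`
#'   (`"cdna"`/`"gdna"`), `residues` -- the observable input of the
#'   pipeline;
#' * `truth`: ground truth (see below) that no pipeline stage may read;
#' * `run_id`: hash identifying the run.
#'
#' `truth` contains: per-locus founder cDNA, the allele pool (genomic and
#' cDNA sequence, exon coordinates, intron repeat copy numbers per
#' allele), per-individual genotypes (at most two alleles per carried
#' locus), the emitted clone-to-allele map, and the configuration.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_preserved_seed(config$seed, {
    ex_len <- config$exon_lengths
    k <- length(ex_len)
    orf_len <- sum(ex_len) - config$utr5_len - config$utr3_len
    orf_start <- config$utr5_len                      # 0-based on cDNA
    root_cdna <- paste0(random_utr(config$utr5_len),
                        random_orf(orf_len %/% 3L),
                        random_utr(config$utr3_len))
    # PBR codons: exons 2..3 on the cDNA, clipped to the ORF
    ex_ends <- cumsum(ex_len)
    ex_starts <- c(0L, ex_ends[-k])
    pbr_iv <- c(max(ex_starts[[2]], orf_start), min(ex_ends[[3]], orf_start + orf_len))
    pbr_codons <- seq.int((pbr_iv[[1]] - orf_start) %/% 3L + 1L,
                          ((pbr_iv[[2]] - orf_start) + 2L) %/% 3L)

    n_mut_locus <- round(config$locus_divergence * orf_len)
    n_mut_allele_base <- config$allele_divergence * orf_len
    loci <- vector("list", config$n_loci)
    for (l in seq_len(config$n_loci)) {
      # between-locus divergence carries the same PBR selection signature
      # as within-locus divergence: paralogs diversified under selection
      founder_cdna <- mutate_orf(root_cdna, orf_start, orf_len, n_mut_locus,
                                 pbr_codons, config$pbr_multiplier)
      copies <- vapply(seq_along(config$intron_base_lengths), function(i) {
        rng <- config$intron_copy_range[i, ]
        if (is.na(config$intron_repeat_units[[i]])) 0L else
          as.integer(rng[[1]] + sample.int(rng[[2]] - rng[[1]] + 1L, 1L) - 1L)
      }, integer(1))
      founder_introns <- vapply(seq_along(copies), function(i) {
        build_intron(config$intron_base_lengths[[i]], config$intron_repeat_units[[i]],
                     copies[[i]])
      }, character(1))
      alleles <- vector("list", config$alleles_per_locus)
      for (a in seq_len(config$alleles_per_locus)) {
        n_mut <- stats::rpois(1L, n_mut_allele_base)
        cdna <- mutate_orf(founder_cdna, orf_start, orf_len, n_mut,
                           pbr_codons, config$pbr_multiplier)
        introns <- vapply(founder_introns, mutate_neutral, character(1),
                          rate = config$intron_divergence)
        # reassert canonical termini (scaffold mutation may have hit them)
        introns <- vapply(introns, function(s) {
          paste0("GT", substr(s, 3L, nchar(s) - 2L), "AG")
        }, character(1), USE.NAMES = FALSE)
        exons <- substring(cdna, ex_starts + 1L, ex_ends)
        gdna <- paste0(paste(vapply(seq_len(k), function(i) {
          paste0(exons[[i]], if (i < k) introns[[i]] else "")
        }, character(1)), collapse = ""))
        iw <- nchar(introns)
        ex_g_start <- cumsum(c(0L, (ex_len + c(iw, 0L))[-k]))
        alleles[[a]] <- list(
          name = sprintf("L%dA%d", l, a),
          cdna = cdna, gdna = gdna,
          exons = cbind(start = ex_g_start, end = ex_g_start + ex_len),
          intron_copies = copies
        )
      }
      loci[[l]] <- list(founder_cdna = founder_cdna, alleles = alleles,
                        intron_copies = copies)
    }
    allele_index <- do.call(rbind, lapply(seq_len(config$n_loci), function(l) {
      data.frame(locus = l, idx = seq_len(config$alleles_per_locus),
                 name = vapply(loci[[l]]$alleles, `[[`, character(1), "name"),
                 stringsAsFactors = FALSE)
    }))

    genotypes <- list()
    for (ind in seq_len(config$n_individuals)) {
      ind_id <- sprintf("ind%02d", ind)
      for (l in seq_len(config$n_loci)) {
        if (stats::runif(1) < config$missing_prob) next
        picked <- sample.int(config$alleles_per_locus, 2L, replace = TRUE)
        genotypes[[length(genotypes) + 1L]] <- data.frame(
          individual_id = ind_id, locus = l,
          allele = vapply(picked, function(a) loci[[l]]$alleles[[a]]$name, character(1)),
          stringsAsFactors = FALSE
        )
      }
    }
    genotypes <- if (length(genotypes)) do.call(rbind, genotypes) else {
      data.frame(individual_id = character(0), locus = integer(0), allele = character(0))
    }

    clone_rows <- list()
    clone_map <- list()
    counter <- 0L
    for (ind_id in unique(genotypes$individual_id)) {
      sub <- genotypes[genotypes$individual_id == ind_id, , drop = FALSE]
      for (al in sort(unique(sub$allele))) {
        rec <- loci[[allele_index$locus[allele_index$name == al]]]$alleles[[
          allele_index$idx[allele_index$name == al]]]
        depth <- config$clone_depth[[1]] +
          sample.int(config$clone_depth[[2]] - config$clone_depth[[1]] + 1L, 1L) - 1L
        for (src in c("cdna", "gdna")) {
          template <- if (src == "cdna") rec$cdna else rec$gdna
          for (d in seq_len(depth)) {
            counter <- counter + 1L
            clone_rows[[counter]] <- data.frame(
              clone_id = sprintf("clone%05d", counter),
              individual_id = ind_id, source = src,
              residues = mutate_neutral(template, config$error_rate),
              stringsAsFactors = FALSE
            )
            clone_map[[counter]] <- data.frame(
              clone_id = sprintf("clone%05d", counter), allele = al, source = src,
              stringsAsFactors = FALSE
            )
          }
        }
      }
    }
    clones <- do.call(rbind, clone_rows)
    truth <- list(
      schema = "mhcloci-sim-truth/1",
      config = unclass(config),
      n_loci = config$n_loci,
      loci = lapply(loci, function(l) {
        list(
          founder_cdna = l$founder_cdna,
          intron_copies = l$intron_copies,
          alleles = lapply(l$alleles, function(a) {
            list(name = a$name, cdna = a$cdna, gdna = a$gdna,
                 exons = a$exons, intron_copies = a$intron_copies)
          })
        )
      }),
      genotypes = genotypes,
      clone_map = do.call(rbind, clone_map)
    )
    run_id <- rlang::hash(truth)
    truth$run_id <- run_id
    structure(list(clones = clones, truth = truth, run_id = run_id),
              class = "sim_result")
  })
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "<sim_result %s> %d loci, %d individuals, %d clones\n",
    substr(x$run_id, 1L, 8L), x$truth$n_loci,
    length(unique(x$clones$individual_id)), nrow(x$clones)
  ))
  invisible(x)
}

#' All distinct allele sequences actually carried by at least one
#' simulated individual
#'
#' @param sim A `sim_result`.
#' @param source `"cdna"` or `"gdna"`.
#' @return Named character vector (names = truth allele names).
#' @export
sim_carried_alleles <- function(sim, source = c("cdna", "gdna")) {
  source <- match.arg(source)
  carried <- unique(sim$truth$genotypes$allele)
  seqs <- character(0)
  for (l in sim$truth$loci) {
    for (a in l$alleles) {
      if (a$name %in% carried) seqs[[a$name]] <- if (source == "cdna") a$cdna else a$gdna
    }
  }
  seqs
}

#' Simulate a neutral codon alignment
#'
#' Sequences evolve independently from a common random stop-free root by
#' uniform substitution: every position and every alternative base is
#' equally likely, with the single constraint that a substitution creating
#' a stop codon is rejected (stop codons never appear in the coding
#' sequences under study). Because rates are equal at synonymous and
#' nonsynonymous sites, dN = dS in expectation -- the null hypothesis of
#' the codon test holds, which makes this generator the reference for
#' checking the test's type-I error rate.
#'
#' @param n_seq Number of sequences.
#' @param n_codons Codons per sequence.
#' @param subs_rate Expected substitutions per site from the root per
#'   sequence (default 0.02, i.e. about 4% pairwise divergence).
#' @param seed Seed.
#' @return Character matrix of codons (rows = sequences).
#' @export
simulate_neutral_codons <- function(n_seq = 20L, n_codons = 200L,
                                    subs_rate = 0.02, seed = 1L) {
  with_preserved_seed(seed, {
    sc <- sense_codons()
    root <- sample(sc, n_codons, replace = TRUE)
    mat <- matrix("", nrow = n_seq, ncol = n_codons)
    n_nt <- 3L * n_codons
    for (i in seq_len(n_seq)) {
      cods <- root
      k <- stats::rbinom(1L, n_nt, subs_rate)
      placed <- 0L
      guard <- 0L
      while (placed < k && guard < 50L * k + 50L) {
        guard <- guard + 1L
        p <- sample.int(n_nt, 1L)
        ci <- (p - 1L) %/% 3L + 1L
        off <- (p - 1L) %% 3L + 1L
        chars <- strsplit(cods[[ci]], "")[[1]]
        alt <- sample(setdiff(BASES, chars[[off]]), 1L)
        chars[[off]] <- alt
        cand <- paste(chars, collapse = "")
        if (cand %in% STOP_CODONS) next
        cods[[ci]] <- cand
        placed <- placed + 1L
      }
      mat[i, ] <- cods
    }
    rownames(mat) <- sprintf("seq%02d", seq_len(n_seq))
    mat
  })
}

#' Write a simulated dataset to disk
#'
#' Emits the clone FASTA (+ `individual=` tags), the clone metadata TSV
#' (same dialect as real-data inputs) and the truth JSON.
#'
#' @param sim A `sim_result`.
#' @param dir Output directory.
#' @return Named character vector of the files written, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "clones.fasta")
  records <- lapply(seq_len(nrow(sim$clones)), function(i) {
    r <- sim$clones[i, ]
    seq_record(r$clone_id, r$residues,
               description = sprintf("individual=%s source=%s", r$individual_id, r$source))
  })
  write_fasta(records, fa)
  meta <- file.path(dir, "clones.tsv")
  write_clone_metadata(sim$clones[c("clone_id", "individual_id", "source")], meta)
  tj <- file.path(dir, "truth.json")
  writeLines(as.character(jsonlite::toJSON(sim$truth, auto_unbox = TRUE, pretty = TRUE,
                                           digits = NA)), tj)
  invisible(c(clones_fasta = fa, clones_tsv = meta, truth_json = tj))
}

#' Score pipeline outputs against simulator truth
#'
#' @param outputs List with any of: `alleles` (character vector of
#'   recovered sequences, per source), `min_locus_estimate`, `models`
#'   (named list of `gene_model`s for recovered genomic alleles), and
#'   `run_id`.
#' @param truth The `truth` element of the matching `sim_result`.
#' @return List of class `sim_scorecard`: `allele_recovery` (fraction of
#'   carried truth alleles recovered exactly), `locus_count_error`
#'   (signed, estimate minus truth), `exon_exactness` (fraction of
#'   annotated alleles whose exon coordinates match truth exactly; `NA`
#'   when no models are supplied).
#' @export
truth_compare <- function(outputs, truth) {
  if (!is.null(outputs$run_id) && !identical(outputs$run_id, truth$run_id)) {
    stop("truth_compare: outputs and truth come from different runs (",
         outputs$run_id, " vs ", truth$run_id, ")")
  }
  carried <- unique(truth$genotypes$allele)
  truth_seqs <- list(cdna = character(0), gdna = character(0))
  truth_exons <- list()
  for (l in truth$loci) {
    for (a in l$alleles) {
      if (!(a$name %in% carried)) next
      truth_seqs$cdna[[a$name]] <- a$cdna
      truth_seqs$gdna[[a$name]] <- a$gdna
      truth_exons[[a$name]] <- a$exons
    }
  }
  allele_recovery <- NA_real_
  if (!is.null(outputs$alleles)) {
    got <- unique(toupper(outputs$alleles))
    want <- unique(unlist(truth_seqs, use.names = FALSE))
    allele_recovery <- mean(want %in% got)
  }
  locus_count_error <- if (!is.null(outputs$min_locus_estimate)) {
    as.integer(outputs$min_locus_estimate) - truth$n_loci
  } else NA_integer_
  exon_exactness <- NA_real_
  if (!is.null(outputs$models) && length(outputs$models)) {
    by_seq <- stats::setNames(names(truth_seqs$gdna), truth_seqs$gdna)
    hits <- vapply(names(outputs$models), function(nm) {
      m <- outputs$models[[nm]]
      gseq <- outputs$model_seqs[[nm]]
      tn <- if (!is.null(gseq)) by_seq[[gseq]] else nm
      if (is.null(tn) || is.na(tn) || is.null(truth_exons[[tn]])) return(NA)
      identical(unname(m$exons[, "start"]), unname(as.integer(truth_exons[[tn]][, "start"]))) &&
        identical(unname(m$exons[, "end"]), unname(as.integer(truth_exons[[tn]][, "end"])))
    }, logical(1))
    exon_exactness <- mean(hits, na.rm = TRUE)
  }
  structure(
    list(allele_recovery = allele_recovery,
         locus_count_error = locus_count_error,
         exon_exactness = exon_exactness),
    class = "sim_scorecard"
  )
}

#' @export
print.sim_scorecard <- function(x, ...) {
  cat(sprintf(
    "<sim_scorecard> allele recovery %.3f; locus-count error %s; exon exactness %s\n",
    x$allele_recovery,
    if (is.na(x$locus_count_error)) "NA" else sprintf("%+d", x$locus_count_error),
    if (is.na(x$exon_exactness)) "NA" else sprintf("%.3f", x$exon_exactness)
  ))
  invisible(x)
}
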