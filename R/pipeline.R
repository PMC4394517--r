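#' Configuration of a composite pipeline run
#'
#' @param clones Clone table (`clone_id`, `individual_id`, `source`,
#'   `residues`), e.g. from a simulation; alternatively give
#'   `clones_fasta` + `clones_tsv` paths to load real data (FASTA of clone
#'   sequences plus the metadata sidecar).
#' @param clones_fasta,clones_tsv Input file paths (used when `clones` is
#'   `NULL`).
#' @param out_dir Output directory for the report bundle.
#' @param min_support Clone-support threshold for allele validation.
#' @param prefix Allele nomenclature prefix.
#' @param n_bootstrap Bootstrap replicates of the selection test.
#' @param outlier_quantile Outlier quantile of the grouping stage.
#' @param min_purity Tandem-repeat purity threshold.
#' @param seed Seed for every random element of the run (recorded in the
#'   summary).
#' @return A list of class `run_config`.
#' @export
run_config <- function(clones = NULL, clones_fasta = NULL, clones_tsv = NULL,
                       out_dir = tempfile("mhcloci_run_"),
                       min_support = 3L, prefix = "Allele",
                       n_bootstrap = 1000L, outlier_quantile = 0.90,
                       min_purity = 0.85, seed = 1L) {
  structure(
    list(clones = clones, clones_fasta = clones_fasta, clones_tsv = clones_tsv,
         out_dir = out_dir, min_support = as.integer(min_support), prefix = prefix,
         n_bootstrap = as.integer(n_bootstrap), outlier_quantile = outlier_quantile,
         min_purity = min_purity, seed = as.integer(seed)),
    class = "run_config"
  )
}

config_hash <- function(config) {
  rlang::hash(unclass(config))
}

stamp_lines <- function(config) {
  c(sprintf("# mhcloci %s", as.character(utils::packageVersion("mhcloci"))),
    sprintf("# config_hash %s seed %d", config_hash(config), config$seed))
}

write_stamped_tsv <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(stamp_lines(config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full locus-inference pipeline
#'
#' Executes validate -> annotate -> polymorphism/selection -> loci ->
#' repeats over a clone dataset and writes every module's outputs plus a
#' summary JSON into `config$out_dir`. The summary (the headline
#' minimum-locus estimate and the per-region selection statistics) is
#' written last: a run that fails at any stage aborts with the stage name
#' and leaves the partial outputs but no summary. Reruns with an
#' identical configuration produce a byte-identical summary.
#'
#' @param config A [run_config()].
#' @return A list of class `pipeline_result` with elements `alleles`
#'   (allele_set), `models`, `polymorphism`, `selection`, `grouping`,
#'   `intron_table`, `summary` (the summary document) and `files`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  clones <- config$clones
  if (is.null(clones)) {
    if (is.null(config$clones_fasta) || is.null(config$clones_tsv)) {
      stop("run_pipeline: provide either `clones` or both `clones_fasta` and `clones_tsv`")
    }
    records <- read_fasta(config$clones_fasta)
    meta <- read_clone_metadata(config$clones_tsv)
    seqs <- seq_strings(records)
    miss <- setdiff(meta$clone_id, names(seqs))
    if (length(miss)) stop("clones in metadata but not in FASTA: ", paste(miss, collapse = ", "))
    clones <- data.frame(clone_id = meta$clone_id,
                         individual_id = meta$individual_id,
                         source = meta$source,
                         residues = unname(seqs[meta$clone_id]),
                         stringsAsFactors = FALSE)
  }
  if (!is.data.frame(clones) || nrow(clones) == 0L) {
    stop("run_pipeline: empty input; nothing to validate")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  files <- character(0)

  ## validate -------------------------------------------------------------
  aset <- stage("validate", collapse_clones(clones, config$min_support, config$prefix))
  files <- c(files, write_allele_set(aset, config$out_dir))
  cdna <- aset$alleles[aset$alleles$source == "cdna", , drop = FALSE]
  gdna <- aset$alleles[aset$alleles$source == "gdna", , drop = FALSE]

  ## annotate -------------------------------------------------------------
  models <- list()
  model_seqs <- character(0)
  exon_seqs <- character(0)
  if (nrow(gdna) && nrow(cdna)) {
    models <- stage("annotate", {
      out <- list()
      for (i in seq_len(nrow(gdna))) {
        grec <- seq_record(gdna$allele_name[[i]], gdna$residues[[i]])
        # same-allele cDNAs share the genomic 5' end (exon 1); try those first
        pre <- substr(gdna$residues[[i]], 1L, 40L)
        try_order <- order(substr(cdna$residues, 1L, 40L) != pre)
        for (j in seq_len(nrow(cdna))[try_order]) {
          crec <- seq_record(cdna$allele_name[[j]], cdna$residues[[j]])
          m <- tryCatch(spliced_align(crec, grec), unannotatable_error = function(e) NULL)
          if (!is.null(m)) { out[[gdna$allele_name[[i]]]] <- m; break }
        }
      }
      out
    })
    for (nm in names(models)) {
      g <- gdna$residues[[match(nm, gdna$allele_name)]]
      model_seqs[[nm]] <- g
      ex <- models[[nm]]$exons
      exon_seqs[[nm]] <- paste(substring(g, ex[, "start"] + 1L, ex[, "end"]), collapse = "")
      files <- c(files, export_gff3(models[[nm]], file.path(config$out_dir, paste0(nm, ".gff3"))))
    }
  }
  ref_model <- if (length(models)) models[[1L]] else NULL

  ## polymorphism & selection ---------------------------------------------
  poly <- NULL
  sel <- list()
  subst <- NULL
  if (nrow(cdna) >= 2L) {
    res <- stage("polymorphism", {
      msa <- build_msa(stats::setNames(cdna$residues, cdna$allele_name))
      orf <- find_orf(cdna$residues[[1L]])
      regions <- if (!is.null(ref_model) && nrow(ref_model$exons) >= 3L) {
        partition_regions(ref_model, "pbr_vs_rest")
      } else NULL
      counts <- polymorphic_sites(msa, regions)
      subs <- do.call(rbind, lapply(seq_len(nrow(cdna))[-1L], function(j) {
        s <- classify_substitutions(cdna$residues[[1L]], cdna$residues[[j]], orf)
        if (nrow(s)) cbind(allele = cdna$allele_name[[j]], s) else NULL
      }))
      tests <- list()
      if (orf$found && !any(grepl("-", msa$aligned, fixed = TRUE))) {
        cod <- codon_alignment(msa, orf)
        if (!is.null(regions)) {
          for (rn in names(regions$codons)) {
            if (length(regions$codons[[rn]]) >= 2L) {
              tests[[rn]] <- selection_test(cod, regions$codons[[rn]],
                                            n_bootstrap = config$n_bootstrap,
                                            seed = config$seed, region_name = rn)
            }
          }
        } else {
          tests[["orf"]] <- selection_test(cod, n_bootstrap = config$n_bootstrap,
                                           seed = config$seed, region_name = "orf")
        }
      }
      list(msa = msa, counts = counts, subs = subs, tests = tests)
    })
    poly <- res$counts
    sel <- res$tests
    subst <- res$subs
    files <- c(files, write_msa_fasta(res$msa, file.path(config$out_dir, "cdna_alleles.aln.fasta")))
    if (!is.null(subst)) {
      files <- c(files, write_stamped_tsv(subst, file.path(config$out_dir, "substitutions.tsv"), config))
    }
    if (length(sel)) {
      stats_df <- do.call(rbind, lapply(sel, function(t) {
        data.frame(region = t$region, n_sites = 3L * t$n_codons,
                   n_polymorphic = if (!is.null(poly$per_region)) {
                     unname(poly$per_region[t$region])
                   } else NA_integer_,
                   dN = t$dN, dS = t$dS, ratio = t$ratio,
                   Z = t$Z, p = t$p, applicable = t$applicable, stringsAsFactors = FALSE)
      }))
      files <- c(files, write_stamped_tsv(stats_df, file.path(config$out_dir, "selection.tsv"), config))
    }
  }

  ## loci ------------------------------------------------------------------
  grouping <- NULL
  nj <- NULL
  locus_src <- NULL
  if (length(exon_seqs) >= 2L) {
    locus_src <- "gdna"
    locus_seqs <- exon_seqs
    locus_geno <- aset$genotypes[aset$genotypes$allele_name %in% names(exon_seqs), , drop = FALSE]
  } else if (nrow(cdna) >= 2L) {
    locus_src <- "cdna"
    locus_seqs <- stats::setNames(cdna$residues, cdna$allele_name)
    locus_geno <- aset$genotypes[aset$genotypes$source == "cdna", , drop = FALSE]
  }
  if (!is.null(locus_src)) {
    grouping <- stage("loci", {
      dm <- p_distance_matrix(locus_seqs)
      g <- constrained_grouping(dm, locus_geno, outlier_quantile = config$outlier_quantile)
      if (nrow(dm) >= 3L) nj <- nj_tree(dm)
      files <- c(files, write_stamped_tsv(
        as.data.frame(as.table(dm), stringsAsFactors = FALSE),
        file.path(config$out_dir, "distances.tsv"), config))
      files <- c(files, write_grouping_json(g, file.path(config$out_dir, "grouping.json")))
      files <- c(files, export_nexus(locus_seqs, file.path(config$out_dir, "alleles.nex")))
      if (!is.null(nj)) {
        nw <- file.path(config$out_dir, "nj_tree.nwk")
        writeLines(nj$newick, nw)
        files <- c(files, nw)
      }
      g
    })
  }

  ## repeats ---------------------------------------------------------------
  intron_table <- NULL
  if (length(models)) {
    intron_table <- stage("repeats", {
      gl <- lapply(stats::setNames(names(models), names(models)),
                   function(nm) model_seqs[[nm]])
      intron_length_table(models, gl, grouping = grouping, min_purity = config$min_purity)
    })
    files <- c(files, write_stamped_tsv(intron_table,
                                        file.path(config$out_dir, "intron_table.tsv"), config))
    intron_seqs <- unlist(lapply(names(models), function(nm) {
      intr <- extract_introns(models[[nm]], seq_record(nm, model_seqs[[nm]]))
      stats::setNames(intr$residues, paste0(nm, ".intron", intr$intron))
    }))
    if (length(intron_seqs)) {
      files <- c(files, write_stamped_tsv(
        repeats_table(intron_seqs, min_purity = config$min_purity),
        file.path(config$out_dir, "repeats.tsv"), config))
    }
  }

  ## summary (written last; atomic headline) --------------------------------
  counts <- allele_counts(aset$genotypes)
  summary_doc <- list(
    tool = "mhcloci",
    version = as.character(utils::packageVersion("mhcloci")),
    config_hash = config_hash(config),
    seed = config$seed,
    n_clones = nrow(clones),
    n_alleles = nrow(aset$alleles),
    allele_counts_per_individual = as.list(counts),
    min_locus_bound = if (length(counts)) min_locus_bound(counts) else NA,
    min_locus_estimate = if (!is.null(grouping)) grouping$min_locus_estimate else NA,
    n_groups = if (!is.null(grouping)) length(grouping$groups) else NA,
    unassigned = if (!is.null(grouping)) grouping$unassigned else character(0),
    polymorphic_sites = if (!is.null(poly)) poly else NA,
    selection = lapply(sel, function(t) {
      list(region = t$region, dN = t$dN, dS = t$dS, ratio = t$ratio,
           Z = t$Z, p = t$p, applicable = t$applicable)
    }),
    intron_lengths = if (!is.null(intron_table)) {
      stats::aggregate(length ~ intron, intron_table,
                       function(x) paste(sort(unique(x)), collapse = ","))
    } else NULL
  )
  summary_path <- file.path(config$out_dir, "summary.json")
  writeLines(as.character(jsonlite::toJSON(summary_doc, auto_unbox = TRUE, pretty = TRUE,
                                           digits = NA, null = "null", na = "null")),
             summary_path)
  files <- c(files, summary = summary_path)

  structure(
    list(alleles = aset, models = models, model_seqs = model_seqs,
         polymorphism = poly, substitutions = subst, selection = sel,
         grouping = grouping, nj = nj, intron_table = intron_table,
         summary = summary_doc, files = files),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> %d allele(s); min locus estimate %s; %d file(s) in bundle\n",
    nrow(x$alleles$alleles),
    if (is.null(x$grouping)) "NA" else x$grouping$min_locus_estimate,
    length(x$files)
  ))
  invisible(x)
}
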