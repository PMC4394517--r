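#' Nei-Gojobori (1986) synonymous / nonsynonymous analysis
#'
#' The NG86 method partitions each codon position into synonymous and
#' nonsynonymous site fractions by enumerating the three possible
#' single-base changes at that position, counts observed differences
#' between codon pairs (averaging multi-hit codons over all minimal
#' substitution pathways that avoid stop codons), corrects the resulting
#' proportions for multiple hits with the Jukes-Cantor formula
#' d = -(3/4) ln(1 - (4/3) p), and tests dN > dS with a Z statistic whose
#' standard error comes from a bootstrap over codon columns.
#'
#' @name ng86
NULL

.ng86_cache <- new.env(parent = emptyenv())

BASES <- c("A", "C", "G", "T")

is_sense_codon <- function(codon) {
  nchar(codon) == 3L && !grepl("[^ACGT]", codon) && !(codon %in% STOP_CODONS)
}

#' Synonymous and nonsynonymous site counts of a codon
#'
#' For each of the three positions the fraction of synonymous sites is the
#' number of synonymous single-base changes divided by the number of
#' single-base changes considered at that position; `s` is the sum of the
#' three fractions and `n = 3 - s`.
#'
#' @param codon A sense codon (no `N`, not a stop).
#' @param stops How single-base changes that create a stop codon enter the
#'   denominator: `"exclude"` (default; they are dropped, the common MEGA
#'   convention) or `"nonsyn"` (they count as nonsynonymous changes).
#' @return Named numeric vector `c(s = , n = )` with `s + n = 3`.
#' @export
ng86_site_counts <- function(codon, stops = c("exclude", "nonsyn")) {
  stops <- match.arg(stops)
  codon <- toupper(codon)
  if (!is_sense_codon(codon)) {
    stop("ng86_site_counts: '", codon, "' is not a sense codon (stop or ambiguous)")
  }
  key <- paste0("site:", codon, ":", stops)
  if (!is.null(v <- .ng86_cache[[key]])) return(v)
  aa0 <- translate_codons(codon)
  chars <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    syn <- 0L
    denom <- 0L
    for (b in setdiff(BASES, chars[[pos]])) {
      mut <- chars
      mut[[pos]] <- b
      mcod <- paste(mut, collapse = "")
      if (mcod %in% STOP_CODONS) {
        if (stops == "nonsyn") denom <- denom + 1L
        next
      }
      denom <- denom + 1L
      if (translate_codons(mcod) == aa0) syn <- syn + 1L
    }
    if (denom > 0L) s <- s + syn / denom
  }
  v <- c(s = s, n = 3 - s)
  .ng86_cache[[key]] <- v
  v
}

# Average synonymous/nonsynonymous difference counts between two sense
# codons: all minimal substitution pathways are enumerated, pathways
# passing through a stop codon are excluded, and the remaining pathways are
# weighted equally. If every pathway passes through a stop (possible for
# 2-3 differences), all pathways are used as a fallback.
codon_path_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  key <- paste0("diff:", min(c1, c2), ":", max(c1, c2))
  if (!is.null(v <- .ng86_cache[[key]])) return(v)
  a <- strsplit(c1, "")[[1]]
  b <- strsplit(c2, "")[[1]]
  pos <- which(a != b)
  perms <- permutations_of(pos)
  tally <- function(skip_stops) {
    acc <- c(sd = 0, nd = 0, n_path = 0)
    for (ord in perms) {
      cur <- a
      sd <- 0L; nd <- 0L; ok <- TRUE
      for (p in ord) {
        nxt <- cur
        nxt[[p]] <- b[[p]]
        ncod <- paste(nxt, collapse = "")
        if (skip_stops && ncod %in% STOP_CODONS) { ok <- FALSE; break }
        if (translate_codons(paste(cur, collapse = "")) == translate_codons(ncod)) {
          sd <- sd + 1L
        } else {
          nd <- nd + 1L
        }
        cur <- nxt
      }
      if (ok) acc <- acc + c(sd, nd, 1)
    }
    acc
  }
  acc <- tally(TRUE)
  if (acc[["n_path"]] == 0) acc <- tally(FALSE)
  v <- c(sd = acc[["sd"]] / acc[["n_path"]], nd = acc[["nd"]] / acc[["n_path"]])
  .ng86_cache[[key]] <- v
  v
}

permutations_of <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) out[[length(out) + 1L]] <- c(x[[i]], rest)
  }
  out
}

#' Jukes-Cantor multiple-hit correction
#'
#' @param p Proportion of differing sites.
#' @return `-(3/4) ln(1 - (4/3) p)`; `NA` when `p >= 3/4`, where the
#'   correction is undefined.
#' @export
jukes_cantor <- function(p) {
  d <- p
  d[] <- NA_real_
  ok <- !is.na(p) & p < 0.75
  d[ok] <- -0.75 * log(1 - 4 * p[ok] / 3)
  d
}

sense_codons <- function() setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)

# Synonymous-site lookup over all 61 sense codons, cached per stop
# convention.
site_s_lookup <- function(stops) {
  key <- paste0("lookup:", stops)
  if (!is.null(v <- .ng86_cache[[key]])) return(v)
  sc <- sense_codons()
  v <- vapply(sc, function(cod) ng86_site_counts(cod, stops)[["s"]], numeric(1))
  .ng86_cache[[key]] <- v
  v
}

# Per-codon-column NG86 profile for one sequence pair. Codons containing a
# gap or N, or that are stop codons, in either sequence are dropped for
# that pair (pairwise deletion): their sd/nd/s/n contributions are 0.
# Returns a list of numeric vectors sd, nd, s, n (length = n codons) plus
# the dropped-column indices.
ng86_pair_profile <- function(cod_a, cod_b, stops = "exclude") {
  nc <- length(cod_a)
  sd <- nd <- s <- n <- numeric(nc)
  lut <- site_s_lookup(stops)
  sa <- lut[cod_a]
  sb <- lut[cod_b]
  valid <- !is.na(sa) & !is.na(sb)
  s[valid] <- (sa[valid] + sb[valid]) / 2
  n[valid] <- 3 - s[valid]
  for (i in which(valid & cod_a != cod_b)) {
    d <- codon_path_diffs(cod_a[[i]], cod_b[[i]])
    sd[[i]] <- d[["sd"]]
    nd[[i]] <- d[["nd"]]
  }
  list(sd = sd, nd = nd, s = s, n = n, dropped = which(!valid))
}

#' Pairwise NG86 distances between two coding sequences
#'
#' @param a,b Equal-length nucleotide strings (or dna [seq_record]s) whose
#'   length is a multiple of 3. Codons containing gaps or `N`, or stop
#'   codons, in either sequence are dropped pairwise and reported.
#' @param stops Stop-neighbor convention, see [ng86_site_counts()].
#' @return List of class `ng86_pair`: `pS`, `pN` (proportions per site),
#'   `dS`, `dN` (Jukes-Cantor corrected; `NA` with the raw proportion
#'   retained when `p >= 3/4`), the underlying counts `Sd`, `Nd`, `S`,
#'   `N`, and `n_dropped`.
#' @export
ng86_pairwise <- function(a, b, stops = c("exclude", "nonsyn")) {
  stops <- match.arg(stops)
  sa <- if (inherits(a, "seq_record")) a$residues else toupper(a)
  sb <- if (inherits(b, "seq_record")) b$residues else toupper(b)
  if (nchar(sa) != nchar(sb)) stop("sequences must have equal length")
  if (nchar(sa) %% 3L != 0L) stop("sequence length must be a multiple of 3")
  prof <- ng86_pair_profile(split_codons(sa), split_codons(sb), stops)
  Sd <- sum(prof$sd); Nd <- sum(prof$nd)
  S <- sum(prof$s); N <- sum(prof$n)
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  structure(
    list(pS = pS, pN = pN, dS = jukes_cantor(pS), dN = jukes_cantor(pN),
         Sd = Sd, Nd = Nd, S = S, N = N, n_dropped = length(prof$dropped)),
    class = "ng86_pair"
  )
}

with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Codon-based Z-test of positive selection
#'
#' Computes dN and dS as the means of [ng86_pairwise()] over all sequence
#' pairs within a codon region, then tests H1: dN > dS with
#' Z = (dN - dS) / SE(dN - dS). By default the SE comes from a bootstrap
#' over codon columns (columns resampled with replacement, the mean
#' dN - dS recomputed per replicate); an analytic alternative sums the
#' binomial variances of the Jukes-Cantor distances and ignores their
#' covariance. The p-value is the one-tailed normal tail P(Z' > Z), since
#' the hypothesis of interest is positive (diversifying) selection.
#'
#' @param codons Character matrix of aligned codons (rows = sequences,
#'   columns = codon positions), e.g. from [codon_alignment()].
#' @param region Optional integer vector of codon columns to test (e.g. a
#'   `codons` entry of [partition_regions()]); default all columns.
#' @param n_bootstrap Bootstrap replicates for the SE (default 1000).
#' @param seed Seed for the bootstrap; results are reproducible
#'   bit-for-bit given (inputs, n_bootstrap, seed).
#' @param stops Stop-neighbor convention, see [ng86_site_counts()].
#' @param variance `"bootstrap"` (default) or `"analytic"`.
#' @param region_name Label carried into the result.
#' @return List of class `selection_test`: `region`, `dN`, `dS`, `ratio`,
#'   `Z`, `p`, `applicable` (FALSE when the sequences are identical in the
#'   region, in which case the test is reported as not applicable),
#'   `n_bootstrap`, `seed`, `n_seq`, `n_codons`.
#' @export
selection_test <- function(codons, region = NULL, n_bootstrap = 1000L, seed = 1L,
                           stops = c("exclude", "nonsyn"),
                           variance = c("bootstrap", "analytic"),
                           region_name = "all") {
  stops <- match.arg(stops)
  variance <- match.arg(variance)
  stopifnot(is.matrix(codons), nrow(codons) >= 2L)
  if (is.null(region)) region <- seq_len(ncol(codons))
  if (length(region) < 2L) stop("selection_test: region must span at least 2 codons")
  sub <- codons[, region, drop = FALSE]
  nseq <- nrow(sub)
  pairs <- utils::combn(nseq, 2L)
  np <- ncol(pairs)
  nc <- ncol(sub)
  Msd <- Mnd <- Ms <- Mn <- matrix(0, nrow = np, ncol = nc)
  for (k in seq_len(np)) {
    prof <- ng86_pair_profile(sub[pairs[1L, k], ], sub[pairs[2L, k], ], stops)
    Msd[k, ] <- prof$sd; Mnd[k, ] <- prof$nd
    Ms[k, ] <- prof$s;   Mn[k, ] <- prof$n
  }
  pair_stats <- function(Sd, Nd, S, N) {
    pS <- ifelse(S > 0, Sd / S, 0)
    pN <- ifelse(N > 0, Nd / N, 0)
    list(dS = jukes_cantor(pS), dN = jukes_cantor(pN), pS = pS, pN = pN, S = S, N = N)
  }
  obs <- pair_stats(rowSums(Msd), rowSums(Mnd), rowSums(Ms), rowSums(Mn))
  dN <- mean(obs$dN, na.rm = TRUE)
  dS <- mean(obs$dS, na.rm = TRUE)
  result <- list(
    region = region_name, dN = dN, dS = dS,
    ratio = if (dS > 0) dN / dS else NA_real_,
    Z = NA_real_, p = NA_real_, applicable = TRUE,
    n_bootstrap = as.integer(n_bootstrap), seed = as.integer(seed),
    n_seq = nseq, n_codons = nc, variance = variance, stops = stops
  )
  if (all(rowSums(Msd) == 0 & rowSums(Mnd) == 0)) {
    result$applicable <- FALSE
    result$dN <- result$dS <- 0
    result$ratio <- NA_real_
    class(result) <- "selection_test"
    return(result)
  }
  se <- if (variance == "bootstrap") {
    boots <- with_preserved_seed(seed, {
      idx <- matrix(sample.int(nc, nc * n_bootstrap, replace = TRUE), nrow = nc)
      Tm <- apply(idx, 2L, tabulate, nbins = nc)
      st <- pair_stats(Msd %*% Tm, Mnd %*% Tm, Ms %*% Tm, Mn %*% Tm)
      colMeans(st$dN - st$dS, na.rm = TRUE)
    })
    stats::sd(boots, na.rm = TRUE)
  } else {
    # binomial variance of d through the JC transform, averaged over pairs;
    # covariance between dN and dS is ignored
    v_d <- function(p, L) ifelse(L > 0 & p < 0.75, p * (1 - p) / (L * (1 - 4 * p / 3)^2), NA_real_)
    sqrt(mean(v_d(obs$pN, obs$N) + v_d(obs$pS, obs$S), na.rm = TRUE))
  }
  if (is.finite(se) && se > 0) {
    result$Z <- (dN - dS) / se
    result$p <- 1 - stats::pnorm(result$Z)
  }
  class(result) <- "selection_test"
  result
}

#' @export
print.selection_test <- function(x, ...) {
  if (!x$applicable) {
    cat(sprintf("<selection_test> region %s: sequences identical; test not applicable\n", x$region))
    return(invisible(x))
  }
  cat(sprintf(
    "<selection_test> region %s (%d seqs, %d codons): dN = %.4f, dS = %.4f, dN/dS = %s, Z = %.3f, one-tailed p = %.4g\n",
    x$region, x$n_seq, x$n_codons, x$dN, x$dS,
    if (is.na(x$ratio)) "NA" else sprintf("%.3f", x$ratio), x$Z, x$p
  ))
  invisible(x)
}
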