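#' Sequence records
#'
#' A `seq_record` is the light container used throughout the package for a
#' single nucleotide or protein sequence: an identifier, a free-text
#' description (which may carry an `individual=<id>` tag naming the fish the
#' clone was sequenced from), and the residues stored uppercase.
#'
#' @param seq_id Character scalar identifier.
#' @param residues Character scalar; `A/C/G/T/N` for `moltype = "dna"`,
#'   amino-acid one-letter codes plus `*` for `moltype = "protein"`.
#'   Case-insensitive on input, stored uppercase.
#' @param description Free-text description. An `individual=<id>` key, when
#'   present, is parsed into the `individual_id` field.
#' @param moltype `"dna"` or `"protein"`.
#' @return An object of class `seq_record`: a list with fields `seq_id`,
#'   `description`, `residues`, `moltype` and `individual_id` (`NA` when no
#'   tag is present).
#' @export
seq_record <- function(seq_id, residues, description = "", moltype = c("dna", "protein")) {
  moltype <- match.arg(moltype)
  stopifnot(is.character(seq_id), length(seq_id) == 1L, nzchar(seq_id))
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (!nzchar(residues)) {
    stop("seq_record '", seq_id, "': residues must be non-empty")
  }
  alphabet <- if (moltype == "dna") "ACGTN" else "ACDEFGHIKLMNPQRSTVWY*X"
  bad <- gsub(sprintf("[%s]", alphabet), "", residues, fixed = FALSE)
  if (nzchar(bad)) {
    stop(
      "seq_record '", seq_id, "': invalid ", moltype, " characters: ",
      paste(unique(strsplit(bad, "")[[1]]), collapse = ", ")
    )
  }
  structure(
    list(
      seq_id = seq_id,
      description = description,
      residues = residues,
      moltype = moltype,
      individual_id = parse_individual_tag(description)
    ),
    class = "seq_record"
  )
}

#' @export
print.seq_record <- function(x, ...) {
  n <- nchar(x$residues)
  head <- substr(x$residues, 1L, 60L)
  cat(sprintf(
    "<seq_record %s> %s, %d %s%s\n  %s%s\n",
    x$seq_id, x$moltype, n, if (x$moltype == "dna") "nt" else "aa",
    if (is.na(x$individual_id)) "" else paste0(", individual ", x$individual_id),
    head, if (n > 60L) "..." else ""
  ))
  invisible(x)
}

#' @export
format.seq_record <- function(x, ...) {
  sprintf("%s (%d %s)", x$seq_id, nchar(x$residues), if (x$moltype == "dna") "nt" else "aa")
}

parse_individual_tag <- function(description) {
  m <- regmatches(description, regexpr("individual=([^[:space:]]+)", description))
  if (length(m) == 0L || !nzchar(m)) return(NA_character_)
  sub("^individual=", "", m)
}

seq_lengths <- function(records) vapply(records, function(r) nchar(r$residues), integer(1))
seq_ids <- function(records) vapply(records, function(r) r$seq_id, character(1))

#' Extract named sequence strings from a list of records
#' @param records List of [seq_record] objects.
#' @return Named character vector (names = `seq_id`s).
#' @export
seq_strings <- function(records) {
  stats::setNames(vapply(records, function(r) r$residues, character(1)), seq_ids(records))
}

#' Read a FASTA file into a list of sequence records
#'
#' Parsing is delegated to [Biostrings::readBStringSet()] after a cheap
#' structural check so that a headerless file is reported with the offending
#' line number. The part of the header before the first whitespace becomes
#' `seq_id`; the remainder is the description (scanned for `individual=`).
#'
#' @param path Path to a FASTA file. An empty file yields an empty list.
#' @param moltype Alphabet the records are validated against.
#' @return List of [seq_record] objects, in file order.
#' @export
read_fasta <- function(path, moltype = c("dna", "protein")) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  content <- which(nzchar(trimws(lines)))
  if (length(content) == 0L) return(list())
  first <- content[[1L]]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("FASTA parse error at line ", first, ": expected '>' header before sequence data")
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  seqs <- as.character(set)
  lapply(seq_along(set), function(i) {
    header <- headers[[i]]
    id <- sub("[[:space:]].*$", "", header)
    desc <- if (grepl("[[:space:]]", header)) sub("^[^[:space:]]+[[:space:]]+", "", header) else ""
    seq_record(id, seqs[[i]], description = desc, moltype = moltype)
  })
}

#' Write sequence records to FASTA
#'
#' Output is wrapped at 70 columns. Headers are `seq_id` followed, when
#' non-empty, by a space and the description.
#'
#' @param records List of [seq_record] objects (or a named character vector
#'   of sequences).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) {
    stopifnot(!is.null(names(records)))
    records <- lapply(names(records), function(nm) seq_record(nm, records[[nm]]))
  }
  headers <- vapply(records, function(r) {
    if (nzchar(r$description)) paste(r$seq_id, r$description) else r$seq_id
  }, character(1))
  set <- Biostrings::BStringSet(vapply(records, function(r) r$residues, character(1)))
  names(set) <- headers
  Biostrings::writeXStringSet(set, filepath = path, width = 70L)
  invisible(path)
}

#' Read clone metadata
#'
#' Sidecar table associating each clone with its individual of origin and
#' template source, with header `clone_id  individual_id  source`.
#'
#' @param path Path to a tab-separated file.
#' @return A data.frame with character columns `clone_id`, `individual_id`
#'   and `source` (`"cdna"` or `"gdna"`).
#' @export
read_clone_metadata <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  required <- c("clone_id", "individual_id", "source")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("clone metadata is missing column(s): ", paste(missing, collapse = ", "))
  }
  bad <- setdiff(unique(df$source), c("cdna", "gdna"))
  if (length(bad)) stop("clone metadata has unknown source value(s): ", paste(bad, collapse = ", "))
  df[required]
}

#' Write clone metadata
#' @param meta Data.frame as returned by [read_clone_metadata()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clone_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Codon -> amino-acid lookup from the standard genetic code; any codon with a
# character outside ACGT (e.g. N) translates to X.
codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- Biostrings::GENETIC_CODE
    tab
  }
})

STOP_CODONS <- c("TAA", "TAG", "TGA")

translate_codons <- function(codons) {
  aa <- unname(codon_table()[codons])
  aa[is.na(aa)] <- "X"
  aa
}

split_codons <- function(dna) {
  n <- nchar(dna) %/% 3L
  if (n == 0L) return(character(0))
  substring(dna, seq(1L, by = 3L, length.out = n), seq(3L, by = 3L, length.out = n))
}

#' Translate a nucleotide sequence
#'
#' Standard genetic code; the trailing partial codon is ignored, stop codons
#' render as `*` and any codon containing `N` as `X`.
#'
#' @param dna Nucleotide string (or a dna [seq_record]).
#' @param frame Reading-frame offset, 0, 1 or 2.
#' @return Protein string; empty when fewer than 3 usable bases remain.
#' @export
translate_dna <- function(dna, frame = 0L) {
  if (inherits(dna, "seq_record")) dna <- dna$residues
  stopifnot(frame %in% 0:2)
  dna <- toupper(dna)
  if (frame > 0L) dna <- substr(dna, frame + 1L, nchar(dna))
  paste(translate_codons(split_codons(dna)), collapse = "")
}

#' Locate the longest open reading frame
#'
#' Scans every ATG in every frame and pairs it with the first in-frame stop
#' codon; returns the longest complete ATG..stop span, ties broken by the
#' smallest start offset. Coordinates are 0-based half-open and include the
#' stop codon, so a 747-nt ORF encodes 248 residues plus the stop.
#'
#' @param cdna A dna [seq_record] or nucleotide string.
#' @return A list of class `orf_annotation` with fields `found` (logical),
#'   `start`, `end` (0-based half-open on the cDNA), `protein` (translated
#'   residues, stop excluded). When no complete ORF exists, `found` is
#'   `FALSE` and the other fields are `NA` -- an explicit result, not an
#'   error.
#' @export
find_orf <- function(cdna) {
  if (inherits(cdna, "seq_record")) {
    stopifnot(cdna$moltype == "dna")
    dna <- cdna$residues
  } else {
    dna <- toupper(cdna)
  }
  n <- nchar(dna)
  no_orf <- structure(
    list(found = FALSE, start = NA_integer_, end = NA_integer_, protein = NA_character_),
    class = "orf_annotation"
  )
  if (n < 6L) return(no_orf)
  starts <- as.integer(gregexpr("ATG", dna, fixed = TRUE)[[1]])
  if (starts[1] == -1L) return(no_orf)
  best <- NULL
  for (fr in 0:2) {
    codon_starts <- seq.int(fr + 1L, n - 2L, by = 3L)
    if (length(codon_starts) == 0L) next
    codons <- substring(dna, codon_starts, codon_starts + 2L)
    stop_idx <- which(codons %in% STOP_CODONS)
    atg_idx <- which(codons == "ATG")
    if (length(stop_idx) == 0L || length(atg_idx) == 0L) next
    # first stop at or after each ATG (in codon units)
    nxt <- stop_idx[findInterval(atg_idx - 1L, stop_idx) + 1L]
    ok <- !is.na(nxt)
    for (j in which(ok)) {
      s <- codon_starts[atg_idx[j]] - 1L          # 0-based start
      e <- codon_starts[nxt[j]] + 2L              # 0-based exclusive end
      len <- e - s
      if (is.null(best) || len > best$len || (len == best$len && s < best$s)) {
        best <- list(s = s, e = e, len = len)
      }
    }
  }
  if (is.null(best)) return(no_orf)
  protein <- translate_dna(substr(dna, best$s + 1L, best$e - 3L))
  structure(
    list(found = TRUE, start = best$s, end = best$e, protein = protein),
    class = "orf_annotation"
  )
}

#' @export
print.orf_annotation <- function(x, ...) {
  if (!x$found) {
    cat("<orf_annotation> no complete ORF\n")
  } else {
    cat(sprintf(
      "<orf_annotation> %d..%d (1-based %d-%d), %d nt, %d aa\n",
      x$start, x$end, x$start + 1L, x$end, x$end - x$start, nchar(x$protein)
    ))
  }
  invisible(x)
}
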