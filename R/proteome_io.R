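#' @importFrom utils read.delim write.table head tail
NULL

# The 20 canonical residues. Ambiguity codes (B, J, Z, X) and the rare
# translated residues (O, U) are rejected up front so that downstream mass
# arithmetic never sees them.
CANONICAL_RESIDUES <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

check_sequence <- function(sequence, label = "sequence") {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence)) {
    stop(label, " must be a non-empty string", call. = FALSE)
  }
  residues <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!(residues %in% CANONICAL_RESIDUES))
  if (length(bad) > 0L) {
    stop(
      label, " contains non-canonical residue '", residues[bad[1L]],
      "' at position ", bad[1L],
      call. = FALSE
    )
  }
  invisible(sequence)
}

#' Read a protein database from FASTA
#'
#' Parses a standard (wrapped or unwrapped) FASTA file into a protein table.
#' The accession is the first whitespace-delimited token of each header; a
#' gene symbol is extracted from a `GN=` token when present.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `protein_id`, `gene_symbol` (empty
#'   string when the header carries no `GN=` token), `sequence` (uppercase)
#'   and `description`.
#' @details Sequences are validated against the 20 canonical amino-acid
#'   letters; ambiguity codes such as B, J, O, U, X or Z raise an error
#'   naming the record and position. Duplicate accessions are an error.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("FASTA file is empty: ", path, call. = FALSE)
  headers <- names(seqs)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1L), 1L)
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop("FASTA header without an accession in ", path, call. = FALSE)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop(
      "duplicate protein_id in ", path, ": ",
      paste(dup, collapse = ", "),
      call. = FALSE
    )
  }
  gene <- regmatches(headers, regexpr("GN=[^[:space:]]+", headers))
  gene_symbol <- character(length(headers))
  has_gn <- grepl("GN=", headers, fixed = TRUE)
  gene_symbol[has_gn] <- sub("^GN=", "", gene)
  description <- sub("^\\S+\\s*", "", headers)
  sequence <- toupper(gsub("[[:space:]]", "", as.character(seqs)))
  for (i in seq_along(sequence)) {
    check_sequence(sequence[i], label = paste0("record '", ids[i], "'"))
  }
  data.frame(
    protein_id = ids,
    gene_symbol = gene_symbol,
    sequence = sequence,
    description = description,
    stringsAsFactors = FALSE
  )
}

#' Write a protein table to FASTA
#'
#' @param proteins A data.frame as returned by [read_fasta()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  stopifnot(all(c("protein_id", "sequence") %in% names(proteins)))
  gene <- if ("gene_symbol" %in% names(proteins)) proteins$gene_symbol else ""
  desc <- if ("description" %in% names(proteins)) proteins$description else ""
  header <- trimws(paste0(
    proteins$protein_id,
    ifelse(nzchar(gene), paste0(" GN=", gene), ""),
    ifelse(nzchar(desc), paste0(" ", desc), "")
  ))
  set <- Biostrings::BStringSet(proteins$sequence)
  names(set) <- header
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

# 0-based cleavage points of a tryptic digest: position i means a cut between
# residue i and i+1. Trypsin cuts C-terminal to K/R; with the Keil rule a
# K/R followed by proline is not cut.
tryptic_cut_points <- function(residues, proline_rule = FALSE) {
  n <- length(residues)
  if (n == 0L) return(integer(0))
  is_kr <- residues %in% c("K", "R")
  cut <- which(is_kr)
  cut <- cut[cut < n]
  if (proline_rule && length(cut) > 0L) {
    cut <- cut[residues[cut + 1L] != "P"]
  }
  cut
}

#' In-silico tryptic digestion
#'
#' Cleaves a protein sequence C-terminal to every lysine and arginine and
#' enumerates all peptides carrying up to `missed_cleavages` internal
#' cleavage sites, with 1-based inclusive coordinates in the parent.
#'
#' @param sequence Protein sequence (canonical residues only).
#' @param missed_cleavages Maximum number of internal missed cleavage sites
#'   (0 to 5).
#' @param proline_rule If `TRUE`, a K/R followed by proline is not cleaved
#'   (the Keil rule). Default `FALSE`: cleavage strictly C-terminal to K and
#'   R with no exception.
#' @return A data.frame with columns `peptide`, `start`, `end`,
#'   `missed_cleavages`. At `missed_cleavages = 0` the spans partition the
#'   sequence.
#' @export
tryptic_digest <- function(sequence, missed_cleavages = 0L,
                           proline_rule = FALSE) {
  check_sequence(sequence)
  if (missed_cleavages < 0L || missed_cleavages > 5L) {
    stop("missed_cleavages must be between 0 and 5", call. = FALSE)
  }
  residues <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(residues)
  cut <- tryptic_cut_points(residues, proline_rule)
  # base peptide boundaries: starts/ends of the 0-missed-cleavage digest
  starts <- c(1L, cut + 1L)
  ends <- c(cut, n)
  n_base <- length(starts)
  out <- vector("list", missed_cleavages + 1L)
  for (mc in 0:missed_cleavages) {
    i <- seq_len(n_base - mc)
    if (length(i) == 0L) break
    j <- i + mc
    out[[mc + 1L]] <- data.frame(
      peptide = substring(sequence, starts[i], ends[j]),
      start = starts[i],
      end = ends[j],
      missed_cleavages = mc,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Count theoretically observable tryptic peptides
#'
#' Number of fully tryptic peptides (zero missed cleavages) of a protein
#' whose length falls in the observable window. This is the denominator of
#' the weighted spectral count, which normalises spectral counts for
#' protein size.
#'
#' @param sequence Protein sequence.
#' @param min_len,max_len Inclusive length window of peptides counted as
#'   observable. Defaults 7 and 35 residues, the typical detectable tryptic
#'   range.
#' @param proline_rule Passed to [tryptic_digest()].
#' @return A non-negative integer count.
#' @export
count_theoretical_peptides <- function(sequence, min_len = 7L, max_len = 35L,
                                       proline_rule = FALSE) {
  if (min_len < 1L || min_len > max_len) {
    stop("require 1 <= min_len <= max_len", call. = FALSE)
  }
  digest <- tryptic_digest(sequence, missed_cleavages = 0L,
                           proline_rule = proline_rule)
  len <- nchar(digest$peptide)
  sum(len >= min_len & len <= max_len)
}

#' Sequence coverage by a set of peptides
#'
#' Fraction of parent residues covered by the union of all occurrences of
#' the given peptides. Overlapping occurrences are merged; peptides absent
#' from the parent contribute nothing.
#'
#' @param sequence Parent protein sequence.
#' @param peptides Character vector of peptide sequences (may be empty).
#' @return Covered fraction in \[0, 1\].
#' @export
sequence_coverage <- function(sequence, peptides) {
  check_sequence(sequence)
  peptides <- unique(peptides[nzchar(peptides)])
  n <- nchar(sequence)
  if (length(peptides) == 0L) return(0)
  covered <- logical(n)
  for (pep in peptides) {
    hits <- gregexpr(pep, sequence, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) next
    for (s in hits) {
      covered[s:(s + nchar(pep) - 1L)] <- TRUE
    }
  }
  sum(covered) / n
}

#' Is a peptide unique within a protein database?
#'
#' A peptide is unique when it occurs as a substring of exactly one
#' protein's sequence. Multiple occurrences within the same protein still
#' count as unique (uniqueness is per protein). Peptides are compared
#' literally; no I/L equivalencing is applied.
#'
#' @param peptide Peptide sequence (non-empty).
#' @param proteins Protein table as returned by [read_fasta()].
#' @return `TRUE` iff exactly one protein contains the peptide.
#' @export
is_unique_peptide <- function(peptide, proteins) {
  if (!nzchar(peptide)) stop("peptide must be non-empty", call. = FALSE)
  if (nrow(proteins) == 0L) stop("protein database is empty", call. = FALSE)
  hits <- vapply(
    proteins$sequence,
    function(s) grepl(peptide, s, fixed = TRUE),
    logical(1L),
    USE.NAMES = FALSE
  )
  sum(hits) == 1L
}

#' Export peptide spans to TSV
#'
#' @param spans Digest table from [tryptic_digest()] with a `protein_id`
#'   column added.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_spans <- function(spans, path) {
  cols <- c("protein_id", "peptide", "start", "end", "missed_cleavages")
  stopifnot(all(cols %in% names(spans)))
  write_tsv(spans[, cols], path)
  invisible(path)
}
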