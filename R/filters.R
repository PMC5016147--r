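# The three-stage exclusion cascade that separates candidate interactors
# from nonspecific binders in a bait-vs-control pulldown:
#
#   filter 1: proteins detected in the control arm whose bait/control
#             enrichment ratio is below the threshold (default 30) are
#             removed; bait-exclusive proteins always pass. Removal is
#             strict (<30); a ratio of exactly 30 is retained.
#   filter 2: proteins on a list of known affinity-purification
#             contaminants, or sharing a family with a listed contaminant
#             (e.g. other heat-shock proteins, other proteasome subunits),
#             are removed.
#   filter 3: proteins whose reference tissue abundance exceeds the
#             threshold fraction (default 1e-4, i.e. 0.01% of total
#             protein), or sharing a family with such an abundant protein
#             (paralogs, e.g. other actins and tubulins), are removed.
#             Removal is strict (>0.01%); exactly 0.01% is retained, and
#             proteins absent from the reference are retained.
#
# Every protein receives exactly one verdict: retained, or removed at the
# first stage whose rule it trips. The bait itself bypasses all filters.

FILTER_STAGES <- c("retained", "filter1_low_enrichment",
                   "filter2_contaminant", "filter3_abundant")

#' Resolve gene symbols to family identifiers
#'
#' Symbols listed in the family map get their mapped family; unlisted
#' symbols form their own singleton family (the symbol itself).
#'
#' @param symbols Character vector of gene symbols.
#' @param family_map Data.frame with columns `gene_symbol`, `family_id`.
#' @return Character vector of family ids.
#' @export
family_of <- function(symbols, family_map) {
  m <- match(symbols, family_map$gene_symbol)
  ifelse(is.na(m), symbols, family_map$family_id[m])
}

new_decision <- function(protein_id, stage, reason, evidence) {
  data.frame(
    protein_id = protein_id, stage = stage, reason = reason,
    evidence = as.character(evidence), stringsAsFactors = FALSE
  )
}

#' Filter 1: low bait/control enrichment
#'
#' Removes proteins detected in the control arm whose enrichment ratio is
#' strictly below the threshold. Bait-exclusive proteins (infinite ratio)
#' always pass this stage.
#'
#' @param quant Quant table with `ratio` and `detected_in_control`
#'   (see [enrichment_ratio()]).
#' @param threshold Enrichment threshold, default 30.
#' @return Decision table: `protein_id`, `stage`, `reason`, `evidence`.
#' @export
filter_low_enrichment <- function(quant, threshold = 30) {
  removed <- quant$detected_in_control &
    !is.na(quant$ratio) & quant$ratio < threshold
  new_decision(
    quant$protein_id,
    ifelse(removed, "filter1_low_enrichment", "retained"),
    ifelse(removed,
           sprintf("bait/control ratio below %g", threshold),
           "passed enrichment filter"),
    signif(quant$ratio, 6)
  )
}

#' Filter 2: known contaminants and their families
#'
#' Removes proteins whose gene symbol is on the contaminant list, or that
#' share a family with any listed contaminant. Proteins without a gene
#' symbol are matched by protein id against the list (and a message is
#' logged).
#'
#' @param quant Quant table with a `gene_symbol` column.
#' @param contaminants Character vector of contaminant gene symbols.
#' @param family_map Family map (see [family_of()]).
#' @return Decision table.
#' @export
filter_contaminants <- function(quant, contaminants, family_map) {
  sym <- quant$gene_symbol
  no_sym <- is.na(sym) | !nzchar(sym)
  if (any(no_sym)) {
    message(sum(no_sym), " protein(s) without gene symbol matched by id")
    sym[no_sym] <- quant$protein_id[no_sym]
  }
  listed <- sym %in% contaminants
  contaminant_families <- unique(family_of(contaminants, family_map))
  fam <- family_of(sym, family_map)
  related <- !listed & fam %in% contaminant_families
  removed <- listed | related
  new_decision(
    quant$protein_id,
    ifelse(removed, "filter2_contaminant", "retained"),
    ifelse(listed, "listed contaminant",
           ifelse(related, "family of contaminant",
                  "passed contaminant filter")),
    ifelse(listed, sym, ifelse(related, fam, ""))
  )
}

#' Filter 3: abundant tissue proteins and their paralogs
#'
#' Removes proteins whose reference abundance strictly exceeds the
#' threshold fraction, and any protein sharing a family with such an
#' abundant protein. Proteins absent from the reference are retained and
#' flagged.
#'
#' @param quant Quant table with a `gene_symbol` column.
#' @param reference Data.frame with columns `gene_symbol`, `abundance`
#'   (fractions of total protein in \[0, 1\]).
#' @param threshold_fraction Removal threshold, default 1e-4 (0.01%).
#' @param family_map Family map (see [family_of()]).
#' @return Decision table.
#' @export
filter_abundant <- function(quant, reference, threshold_fraction = 1e-4,
                            family_map = NULL) {
  if (is.null(family_map)) {
    family_map <- data.frame(gene_symbol = character(0),
                             family_id = character(0))
  }
  sym <- quant$gene_symbol
  sym[is.na(sym) | !nzchar(sym)] <- quant$protein_id[is.na(sym) | !nzchar(sym)]
  m <- match(sym, reference$gene_symbol)
  abundance <- reference$abundance[m]
  in_ref <- !is.na(m)
  abundant <- in_ref & abundance > threshold_fraction
  abundant_ref <- reference$gene_symbol[reference$abundance >
                                          threshold_fraction]
  abundant_families <- unique(family_of(abundant_ref, family_map))
  fam <- family_of(sym, family_map)
  paralog <- !abundant & fam %in% abundant_families
  removed <- abundant | paralog
  new_decision(
    quant$protein_id,
    ifelse(removed, "filter3_abundant", "retained"),
    ifelse(abundant,
           sprintf("reference abundance above %g", threshold_fraction),
           ifelse(paralog, "paralog of abundant protein",
                  ifelse(in_ref, "passed abundance filter",
                         "not in reference"))),
    ifelse(abundant, signif(abundance, 6), ifelse(paralog, fam, ""))
  )
}

#' Run the three-filter exclusion cascade
#'
#' Applies the low-enrichment, contaminant and abundance filters in order.
#' A protein removed at one stage is never re-examined at a later one, and
#' the bait bypasses all filters. The per-stage tallies are asserted to
#' partition the input.
#'
#' @param quant Quant table with `ratio`, `detected_in_control` and
#'   `gene_symbol` columns.
#' @param contaminants Contaminant gene symbols.
#' @param family_map Family map data.frame (`gene_symbol`, `family_id`).
#' @param reference Reference abundance data.frame (`gene_symbol`,
#'   `abundance`).
#' @param bait_id Protein id of the bait; it is always retained (reason
#'   "bait").
#' @param enrichment_threshold Filter-1 threshold, default 30.
#' @param abundance_threshold Filter-3 threshold fraction, default 1e-4.
#' @return List with `decisions` (one row per input protein), `retained`
#'   (the surviving quant rows, decision columns appended), and `tallies`
#'   (named counts per stage; they sum to the input row count).
#' @export
run_cascade <- function(quant, contaminants, family_map, reference,
                        bait_id = NULL, enrichment_threshold = 30,
                        abundance_threshold = 1e-4) {
  if (nrow(quant) == 0L) {
    tallies <- stats::setNames(integer(length(FILTER_STAGES)), FILTER_STAGES)
    return(list(decisions = new_decision(character(0), character(0),
                                         character(0), character(0)),
                retained = quant, tallies = tallies))
  }
  decisions <- new_decision(quant$protein_id, NA_character_, NA_character_,
                            "")
  is_bait <- !is.null(bait_id) & quant$protein_id %in% bait_id
  decisions$stage[is_bait] <- "retained"
  decisions$reason[is_bait] <- "bait"

  pending <- which(!is_bait)
  apply_stage <- function(decisions, pending, stage_decisions) {
    hit <- stage_decisions$stage != "retained"
    decisions$stage[pending[hit]] <- stage_decisions$stage[hit]
    decisions$reason[pending[hit]] <- stage_decisions$reason[hit]
    decisions$evidence[pending[hit]] <- stage_decisions$evidence[hit]
    list(decisions = decisions, pending = pending[!hit])
  }

  s1 <- filter_low_enrichment(quant[pending, , drop = FALSE],
                              enrichment_threshold)
  st <- apply_stage(decisions, pending, s1)
  s2 <- filter_contaminants(quant[st$pending, , drop = FALSE],
                            contaminants, family_map)
  st <- apply_stage(st$decisions, st$pending, s2)
  s3 <- filter_abundant(quant[st$pending, , drop = FALSE], reference,
                        abundance_threshold, family_map)
  st3 <- apply_stage(st$decisions, st$pending, s3)
  decisions <- st3$decisions
  surviving <- st3$pending
  decisions$stage[surviving] <- "retained"
  decisions$reason[surviving] <-
    s3$reason[match(decisions$protein_id[surviving], s3$protein_id)]

  tallies <- vapply(FILTER_STAGES, function(s) sum(decisions$stage == s),
                    integer(1L))
  stopifnot(sum(tallies) == nrow(quant))  # partition invariant
  retained <- cbind(
    quant[decisions$stage == "retained", , drop = FALSE],
    decisions[decisions$stage == "retained", c("reason"), drop = FALSE]
  )
  rownames(retained) <- NULL
  list(decisions = decisions, retained = retained, tallies = tallies)
}

#' Annotate candidate interactors with kinase status
#'
#' Flags each candidate found on the kinase list and reports the kinase
#' fraction among the non-bait candidates (the bait is excluded from the
#' denominator and from the kinase count).
#'
#' @param candidates Retained quant rows with `gene_symbol`.
#' @param kinases Character vector of kinase gene symbols.
#' @param bait_id Protein id of the bait.
#' @return List with `candidates` (an `is_kinase` column added),
#'   `n_kinases`, `n_non_bait` and `kinase_fraction`.
#' @export
annotate_kinases <- function(candidates, kinases, bait_id = NULL) {
  is_kinase <- candidates$gene_symbol %in% kinases
  is_bait <- !is.null(bait_id) & candidates$protein_id %in% bait_id
  candidates$is_kinase <- is_kinase & !is_bait
  n_non_bait <- sum(!is_bait)
  n_kinases <- sum(candidates$is_kinase)
  list(
    candidates = candidates,
    n_kinases = n_kinases,
    n_non_bait = n_non_bait,
    kinase_fraction = if (n_non_bait > 0L) n_kinases / n_non_bait else 0
  )
}

#' Read a one-column gene-symbol resource (contaminants, kinases)
#' @param path TSV/text file whose first column is `gene_symbol`.
#' @return Character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  df <- read_tsv(path)
  as.character(df[[1L]])
}

#' Read a gene-family map
#' @param path TSV with columns `gene_symbol`, `family_id`.
#' @return Data.frame.
#' @export
read_family_map <- function(path) {
  df <- read_tsv(path)
  stopifnot(all(c("gene_symbol", "family_id") %in% names(df)))
  df
}

#' Read a reference abundance table
#'
#' @param path TSV with columns `gene_symbol`, `abundance` (fractional
#'   abundances of total protein).
#' @return Data.frame; values are checked to lie in \[0, 1\] and to sum to
#'   at most 1 (the reference may cover only part of the proteome).
#' @export
read_reference_abundance <- function(path) {
  df <- read_tsv(path)
  stopifnot(all(c("gene_symbol", "abundance") %in% names(df)))
  if (any(df$abundance < 0 | df$abundance > 1)) {
    stop("abundances must lie in [0, 1]", call. = FALSE)
  }
  if (sum(df$abundance) > 1 + 1e-9) {
    stop("reference abundances sum to more than 1", call. = FALSE)
  }
  df
}
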