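# Protein-inference rules, single-peptide ("one peptide wonder")
# spectrum validation, and a simplified target-decoy FDR.

#' Protein inference from PSMs
#'
#' Accepts proteins with at least `min_peptides` distinct peptides at or
#' above the confidence cutoff; proteins with exactly one distinct
#' qualifying peptide are routed to single-peptide validation; proteins
#' with none are rejected. Decoy PSMs never contribute.
#'
#' @param psms Validated PSM table.
#' @param min_confidence Peptide confidence cutoff, default 99.
#' @param min_peptides Minimum distinct peptides per protein, default 2.
#' @return List with character vectors `accepted`, `single_peptide`,
#'   `rejected`, and a `summary` data.frame (protein_id,
#'   n_distinct_peptides, status).
#' @export
infer_proteins <- function(psms, min_confidence = 99, min_peptides = 2L) {
  psms <- validate_psms(psms)
  all_ids <- sort(unique(psms$protein_id[!psms$is_decoy]))
  keep <- !psms$is_decoy & psms$confidence >= min_confidence
  q <- psms[keep, , drop = FALSE]
  n_distinct <- vapply(
    split(q$peptide, factor(q$protein_id, levels = all_ids)),
    function(p) length(unique(p)), integer(1L)
  )
  status <- ifelse(
    n_distinct >= min_peptides, "accepted",
    ifelse(n_distinct == 1L, "single_peptide", "rejected")
  )
  # a one-peptide protein is accepted outright when min_peptides <= 1
  if (min_peptides <= 1L) status[n_distinct == 1L] <- "accepted"
  summary <- data.frame(
    protein_id = all_ids,
    n_distinct_peptides = as.integer(n_distinct),
    status = status,
    stringsAsFactors = FALSE
  )
  list(
    accepted = all_ids[status == "accepted"],
    single_peptide = all_ids[status == "single_peptide"],
    rejected = all_ids[status == "rejected"],
    summary = summary
  )
}

#' Validate a single-peptide identification against its spectrum
#'
#' Operationalises the manual-inspection criteria for proteins identified
#' by a single peptide:
#' (a) good signal-to-noise: strictly more than half of the matched
#'     fragment ions have S/N > `sn_threshold`, where the noise floor is
#'     the median intensity of peaks not matched to the theoretical b/y
#'     ladder;
#' (b) at least `min_consecutive` consecutive y- or b-ions matched within
#'     one series;
#' (c) every y-ion whose N-terminal residue is a proline has intensity at
#'     or above the median intensity of all matched ions (not applicable
#'     when the peptide has no internal proline).
#'
#' @param spec Spectrum data.frame (`mz`, `intensity`).
#' @param peptide Peptide sequence.
#' @param mods Optional modification table.
#' @param tol Fragment matching tolerance in Th, default 0.05.
#' @param sn_threshold Signal-to-noise threshold, default 3.
#' @param min_consecutive Minimum run of consecutive ladder indices,
#'   default 3.
#' @return List with `criteria` (named logicals; `proline_y_intense` is
#'   `NA` when not applicable), `pass` (all applicable criteria true),
#'   `noise_floor` and the matched-ion table.
#' @export
validate_single_peptide <- function(spec, peptide, mods = NULL, tol = 0.05,
                                    sn_threshold = 3, min_consecutive = 3L) {
  if (is.null(spec) || nrow(spec) == 0L) {
    stop("empty spectrum", call. = FALSE)
  }
  ladder <- fragment_series(peptide, mods)
  base <- ladder[ladder$neutral_loss == 0, , drop = FALSE]
  hit <- match_peaks(base$mz, spec, tol)
  base$matched <- !is.na(hit)
  base$intensity <- ifelse(base$matched, spec$intensity[hit], 0)

  matched_peak_idx <- unique(hit[!is.na(hit)])
  unmatched <- setdiff(seq_len(nrow(spec)), matched_peak_idx)
  noise_floor <- if (length(unmatched) > 0L) {
    stats::median(spec$intensity[unmatched])
  } else {
    0
  }

  matched_ions <- base[base$matched, , drop = FALSE]
  sn_majority <- if (nrow(matched_ions) == 0L) {
    FALSE
  } else if (noise_floor == 0) {
    TRUE
  } else {
    sum(matched_ions$intensity / noise_floor > sn_threshold) >
      nrow(matched_ions) / 2
  }

  longest_run <- function(idx) {
    if (length(idx) == 0L) return(0L)
    idx <- sort(unique(idx))
    runs <- rle(c(1L, diff(idx)) == 1L)
    # diff==1 marks continuation; count maximal consecutive stretch
    max(c(1L, runs$lengths[runs$values] + 1L))
  }
  consecutive_ions <-
    longest_run(matched_ions$index[matched_ions$series == "b"]) >=
      min_consecutive ||
    longest_run(matched_ions$index[matched_ions$series == "y"]) >=
      min_consecutive

  residues <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  n <- length(residues)
  proline_pos <- which(residues == "P")
  proline_pos <- proline_pos[proline_pos > 1L & proline_pos <= n]
  if (length(proline_pos) == 0L) {
    proline_y_intense <- NA
  } else {
    med <- if (nrow(matched_ions) > 0L) {
      stats::median(matched_ions$intensity)
    } else {
      Inf
    }
    # the y ion starting at proline position p is y_{n - p + 1}
    y_idx <- n - proline_pos + 1L
    y_idx <- y_idx[y_idx >= 1L & y_idx <= n - 1L]
    y_int <- vapply(y_idx, function(j) {
      v <- base$intensity[base$series == "y" & base$index == j]
      if (length(v) == 0L) 0 else v
    }, numeric(1L))
    proline_y_intense <- all(y_int >= med)
  }

  criteria <- list(
    sn_majority = sn_majority,
    consecutive_ions = consecutive_ions,
    proline_y_intense = proline_y_intense
  )
  applicable <- !vapply(criteria, is.na, logical(1L))
  pass <- all(unlist(criteria)[applicable])
  list(criteria = criteria, pass = pass, noise_floor = noise_floor,
       ions = base)
}

#' Simplified target-decoy q-values
#'
#' Sorts PSMs by descending score; the FDR at a score threshold is the
#' number of decoys divided by the number of targets at or above it, and
#' the q-value is the running minimum of FDR from the least confident
#' threshold upward. Tied scores share one threshold.
#'
#' @param score Numeric PSM scores (higher is better).
#' @param is_decoy Logical, same length.
#' @return Numeric q-values in \[0, 1\] in the input order, monotone
#'   non-increasing in score.
#' @export
target_decoy_fdr <- function(score, is_decoy) {
  if (length(score) != length(is_decoy)) {
    stop("score and is_decoy lengths differ", call. = FALSE)
  }
  if (!any(is_decoy)) {
    stop("no decoy PSMs: generate decoys from reversed sequences first",
         call. = FALSE)
  }
  if (all(is_decoy)) stop("no target PSMs", call. = FALSE)
  o <- order(score, decreasing = TRUE)
  s <- score[o]
  d <- is_decoy[o]
  cum_decoy <- cumsum(d)
  cum_target <- cumsum(!d)
  # evaluate at the last index of each tie group so a threshold always
  # includes every PSM with that score
  last_of_tie <- rev(!duplicated(rev(s)))
  ends <- which(last_of_tie)
  at <- ends[findInterval(seq_along(s) - 1L, ends) + 1L]
  fdr <- pmin(1, cum_decoy[at] / pmax(1L, cum_target[at]))
  q <- rev(cummin(rev(fdr)))
  out <- numeric(length(score))
  out[o] <- q
  out
}
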