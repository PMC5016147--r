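# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, textbook formulas and
# boolean masks.

# Brute-force tryptic peptide enumeration: every substring whose start is a
# sequence start or preceded by a cleavage point, whose end is a sequence
# end or a cleavage point, with at most `mc` internal cleavage points.
oracle_tryptic_peptides <- function(sequence, mc = 0L,
                                    proline_rule = FALSE) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(res)
  cuts <- which(res %in% c("K", "R"))
  cuts <- cuts[cuts < n]
  if (proline_rule) cuts <- cuts[res[cuts + 1] != "P"]
  bounds <- c(0L, cuts, n)  # cleavage points as 0-based boundaries
  out <- list()
  for (i in seq_len(length(bounds) - 1L)) {
    for (j in (i + 1L):length(bounds)) {
      internal <- j - i - 1L
      if (internal > mc) next
      out[[length(out) + 1L]] <- data.frame(
        peptide = substr(sequence, bounds[i] + 1L, bounds[j]),
        start = bounds[i] + 1L, end = bounds[j],
        missed_cleavages = internal, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

# Textbook Welch two-sample t-test on x vs y (two-sided).
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 /
    (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# Brute-force target-decoy q-values via an exhaustive threshold sweep.
oracle_qvalues <- function(score, is_decoy) {
  fdr_at <- vapply(score, function(s) {
    above <- score >= s
    min(1, sum(is_decoy & above) / max(1, sum(!is_decoy & above)))
  }, numeric(1))
  vapply(seq_along(score), function(i) {
    min(fdr_at[score <= score[i]])
  }, numeric(1))
}

random_peptide <- function(len, residues = names(tapms::RESIDUE_MASSES)) {
  paste(sample(residues, len, replace = TRUE), collapse = "")
}

# minimal PSM row constructor for unit tests
psm <- function(protein_id, peptide = "ELVISLIVESK", group = "bait",
                confidence = 99.5, proc = 1L, tech = 1L, charge = 2L,
                decoy = FALSE, id = NULL) {
  data.frame(
    spectrum_id = id %||% paste0("s", sample.int(1e9, 1)),
    sample_group = group, process_rep = proc, tech_rep = tech,
    peptide = peptide, mods = "", protein_id = protein_id,
    charge = charge, confidence = confidence, is_decoy = decoy,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
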