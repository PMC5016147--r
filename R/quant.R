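# Spectral counting, weighted counts, enrichment ratios, and MS1
# extracted-ion-chromatogram (XIC) quantification.
#
# A spectral count is the number of PSMs (not distinct peptides) assigned
# to a protein. Counts are combined over all process and technical
# replicates within each arm (control vs bait), mirroring a pooled
# two-arm pulldown design. The weighted spectral count divides by the
# number of theoretically observable tryptic peptides, correcting for
# protein size.

SAMPLE_GROUPS <- c("control", "bait")

#' Read a PSM table
#'
#' @param path TSV with columns `spectrum_id`, `sample_group`,
#'   `process_rep`, `tech_rep`, `peptide`, `mods`, `protein_id`, `charge`,
#'   `confidence`, `is_decoy`.
#' @return Validated PSM data.frame.
#' @export
read_psm_table <- function(path) {
  psms <- read_tsv(path)
  validate_psms(psms)
}

#' Write a PSM table
#' @param psms PSM data.frame.
#' @param path Output path.
#' @param extra_comment Optional extra comment line (e.g. the simulation
#'   seed).
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path, extra_comment = NULL) {
  write_tsv(psms, path, extra_comment = extra_comment)
}

#' Validate a PSM table
#'
#' Checks required columns, confidence range, charge, sample-group labels
#' and uniqueness of (sample_group, process_rep, tech_rep, spectrum_id).
#'
#' @param psms PSM data.frame.
#' @return The table, invisibly usable, with `is_decoy` coerced to logical.
#' @export
validate_psms <- function(psms) {
  required <- c("spectrum_id", "sample_group", "process_rep", "tech_rep",
                "peptide", "protein_id", "charge", "confidence", "is_decoy")
  missing <- setdiff(required, names(psms))
  if (length(missing) > 0L) {
    stop("PSM table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad_group <- setdiff(unique(psms$sample_group), SAMPLE_GROUPS)
  if (length(bad_group) > 0L) {
    stop("unknown sample_group label(s): ",
         paste(bad_group, collapse = ", "), call. = FALSE)
  }
  if (any(psms$confidence < 0 | psms$confidence > 100)) {
    stop("confidence must lie in [0, 100]", call. = FALSE)
  }
  if (any(psms$charge < 1L)) stop("charge must be >= 1", call. = FALSE)
  psms$is_decoy <- as.logical(psms$is_decoy)
  key <- paste(psms$sample_group, psms$process_rep, psms$tech_rep,
               psms$spectrum_id)
  if (anyDuplicated(key)) {
    stop("duplicate (sample_group, process_rep, tech_rep, spectrum_id)",
         call. = FALSE)
  }
  psms
}

#' Aggregate PSMs into per-protein spectral counts
#'
#' Counts PSMs with confidence at or above the cutoff, summed over all
#' process and technical replicates within each arm. Decoy PSMs are
#' excluded.
#'
#' @param psms Validated PSM table.
#' @param min_confidence Peptide confidence cutoff (default 99).
#' @return Data.frame with columns `protein_id`, `sc_control`, `sc_bait`.
#' @export
aggregate_spectral_counts <- function(psms, min_confidence = 99) {
  psms <- validate_psms(psms)
  keep <- !psms$is_decoy & psms$confidence >= min_confidence
  psms <- psms[keep, , drop = FALSE]
  ids <- sort(unique(psms$protein_id))
  tab <- table(
    factor(psms$protein_id, levels = ids),
    factor(psms$sample_group, levels = SAMPLE_GROUPS)
  )
  data.frame(
    protein_id = ids,
    sc_control = as.integer(tab[, "control"]),
    sc_bait = as.integer(tab[, "bait"]),
    stringsAsFactors = FALSE
  )
}

#' Weighted spectral counts
#'
#' Divides spectral counts by each protein's number of theoretically
#' observable tryptic peptides. Proteins with zero theoretical peptides
#' get `NA` weighted counts and `wsc_defined = FALSE`; they are flagged,
#' never silently dropped.
#'
#' @param counts Output of [aggregate_spectral_counts()].
#' @param theoretical Data.frame with columns `protein_id`,
#'   `theoretical_peptides`.
#' @return Quant table with `wsc_control`, `wsc_bait`,
#'   `detected_in_control`, `wsc_defined` added.
#' @export
weighted_counts <- function(counts, theoretical) {
  m <- match(counts$protein_id, theoretical$protein_id)
  tp <- theoretical$theoretical_peptides[m]
  if (anyNA(tp)) {
    stop("no theoretical peptide count for: ",
         paste(utils::head(counts$protein_id[is.na(tp)], 5L),
               collapse = ", "),
         call. = FALSE)
  }
  if (any(tp < 0)) stop("theoretical_peptides must be >= 0", call. = FALSE)
  defined <- tp > 0
  out <- counts
  out$theoretical_peptides <- tp
  out$wsc_control <- ifelse(defined, counts$sc_control / tp, NA_real_)
  out$wsc_bait <- ifelse(defined, counts$sc_bait / tp, NA_real_)
  out$wsc_defined <- defined
  out$detected_in_control <- counts$sc_control > 0L
  out
}

#' Bait/control enrichment ratio
#'
#' With the default pseudocount of 0, the ratio is bait/control on weighted
#' (or raw) counts when the protein was detected in the control arm, and
#' `+Inf` for bait-exclusive proteins. Rows with zero counts in both arms
#' get `NA` and `ratio_defined = FALSE`. A positive pseudocount `c` yields
#' the finite ratio `(bait + c) / (control + c)` everywhere.
#'
#' @param quant Quant table from [weighted_counts()].
#' @param pseudocount Non-negative pseudocount, default 0.
#' @param mode `"weighted"` (default) uses weighted counts; `"raw"` uses
#'   plain spectral counts.
#' @return The table with `ratio` and `ratio_defined` columns added, rows
#'   ordered by descending `wsc_bait` then `protein_id`.
#' @export
enrichment_ratio <- function(quant, pseudocount = 0,
                             mode = c("weighted", "raw")) {
  mode <- match.arg(mode)
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  b <- if (mode == "weighted") quant$wsc_bait else quant$sc_bait
  ct <- if (mode == "weighted") quant$wsc_control else quant$sc_control
  defined <- quant$sc_bait > 0L | quant$sc_control > 0L
  if (pseudocount > 0) {
    ratio <- (b + pseudocount) / (ct + pseudocount)
  } else {
    ratio <- ifelse(ct > 0, b / ct, ifelse(b > 0, Inf, NA_real_))
  }
  ratio[!defined] <- NA_real_
  quant$ratio <- ratio
  quant$ratio_defined <- defined
  o <- order(-quant$wsc_bait, quant$protein_id)
  quant <- quant[o, , drop = FALSE]
  rownames(quant) <- NULL
  quant
}

#' Write a quant table
#' @param quant Quant table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(quant, path) {
  write_tsv(quant, path)
}

#' XIC peak area by trapezoidal integration
#'
#' @param rt Strictly increasing retention times (seconds), length >= 2.
#' @param intensity Non-negative intensities, same length.
#' @param window Optional `c(start, end)` in seconds; default the full
#'   trace. The trace is linearly interpolated at the window edges so that
#'   areas are additive over adjacent windows.
#' @return Peak area in intensity * seconds.
#' @export
xic_peak_area <- function(rt, intensity, window = NULL) {
  if (length(rt) != length(intensity) || length(rt) < 2L) {
    stop("rt and intensity must be equal length >= 2", call. = FALSE)
  }
  if (any(diff(rt) <= 0)) {
    stop("retention times must be strictly increasing", call. = FALSE)
  }
  if (any(intensity < 0)) stop("intensities must be >= 0", call. = FALSE)
  if (is.null(window)) window <- range(rt)
  lo <- max(window[1L], rt[1L])
  hi <- min(window[2L], rt[length(rt)])
  if (lo >= hi) stop("window does not overlap the trace", call. = FALSE)
  inside <- rt > lo & rt < hi
  x <- c(lo, rt[inside], hi)
  y <- stats::approx(rt, intensity, xout = x)$y
  pracma::trapz(x, y)
}

#' Per-replicate, per-channel XIC areas
#'
#' Integrates a long-form XIC table per (sample_group, replicate, charge,
#' channel) and reports the per-isotope areas plus their M + M+1 + M+2 sum.
#'
#' @param xic Long-form data.frame with columns `peptide`, `charge`,
#'   `channel` (`"M"`, `"M+1"`, `"M+2"`), `sample_group`, `tech_rep`, `rt`,
#'   `intensity`.
#' @param window Optional retention-time window passed to
#'   [xic_peak_area()].
#' @return Data.frame with one row per (peptide, charge, sample_group,
#'   tech_rep): the three channel areas and `area_total`.
#' @export
xic_areas <- function(xic, window = NULL) {
  required <- c("peptide", "charge", "channel", "sample_group", "tech_rep",
                "rt", "intensity")
  missing <- setdiff(required, names(xic))
  if (length(missing) > 0L) {
    stop("XIC table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  key <- interaction(xic$peptide, xic$charge, xic$sample_group,
                     xic$tech_rep, xic$channel, drop = TRUE)
  parts <- split(xic, key)
  rows <- lapply(parts, function(d) {
    d <- d[order(d$rt), , drop = FALSE]
    data.frame(
      peptide = d$peptide[1L], charge = d$charge[1L],
      sample_group = d$sample_group[1L], tech_rep = d$tech_rep[1L],
      channel = d$channel[1L],
      area = xic_peak_area(d$rt, d$intensity, window),
      stringsAsFactors = FALSE
    )
  })
  long <- do.call(rbind, rows)
  wide_key <- interaction(long$peptide, long$charge, long$sample_group,
                          long$tech_rep, drop = TRUE)
  out <- do.call(rbind, lapply(split(long, wide_key), function(d) {
    area_of <- function(ch) {
      a <- d$area[d$channel == ch]
      if (length(a) == 0L) 0 else sum(a)
    }
    data.frame(
      peptide = d$peptide[1L], charge = d$charge[1L],
      sample_group = d$sample_group[1L], tech_rep = d$tech_rep[1L],
      area_M = area_of("M"), area_M1 = area_of("M+1"),
      area_M2 = area_of("M+2"),
      area_total = sum(d$area),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

welch_p_zero_variance <- function(bait, control) {
  # stats::t.test refuses constant data; define the degenerate limits
  if (isTRUE(all.equal(mean(bait), mean(control)))) {
    list(t = 0, p = 1)
  } else {
    list(t = sign(mean(bait) - mean(control)) * Inf, p = 0)
  }
}

#' MS1 fold change with replicate t-test
#'
#' Fold change is the ratio of arithmetic mean peak areas (bait/control);
#' significance is a two-tailed two-sample t-test on log-transformed areas
#' (Welch by default, pooled-variance Student optional).
#'
#' @param bait_areas,control_areas Replicate peak areas (>= 2 each).
#' @param var_equal `FALSE` (default) for Welch, `TRUE` for pooled
#'   variance.
#' @param area_floor Optional positive floor substituted for non-positive
#'   areas before the log transform.
#' @return List with `fold_change`, `t`, `p`, `n_bait`, `n_control`.
#' @export
ms1_fold_change <- function(bait_areas, control_areas, var_equal = FALSE,
                            area_floor = NULL) {
  if (length(bait_areas) < 2L || length(control_areas) < 2L) {
    stop("need >= 2 replicate areas per arm", call. = FALSE)
  }
  if (!is.null(area_floor)) {
    bait_areas <- pmax(bait_areas, area_floor)
    control_areas <- pmax(control_areas, area_floor)
  }
  if (any(bait_areas <= 0) || any(control_areas <= 0)) {
    stop("non-positive peak area; set a pseudo-area floor via `area_floor`",
         call. = FALSE)
  }
  fc <- mean(bait_areas) / mean(control_areas)
  lb <- log(bait_areas)
  lc <- log(control_areas)
  if (stats::sd(lb) == 0 && stats::sd(lc) == 0) {
    tt <- welch_p_zero_variance(lb, lc)
  } else {
    ht <- stats::t.test(lb, lc, var.equal = var_equal,
                        alternative = "two.sided")
    tt <- list(t = unname(ht$statistic), p = ht$p.value)
  }
  list(fold_change = fc, t = tt$t, p = tt$p,
       n_bait = length(bait_areas), n_control = length(control_areas))
}

#' Quantify a peptide from its XICs
#'
#' Selects the top-ranked precursor (the charge state with the largest
#' total summed area across all replicates) when several charge states are
#' present, then computes the bait/control fold change and t-test from the
#' per-replicate summed M + M+1 + M+2 areas.
#'
#' @param xic Long-form XIC table (see [xic_areas()]).
#' @inheritParams ms1_fold_change
#' @return List with `peptide`, `charge` (the selected precursor),
#'   `fold_change`, `t`, `p`, and the per-replicate `areas` table.
#' @export
ms1_quantify <- function(xic, var_equal = FALSE, area_floor = NULL) {
  areas <- xic_areas(xic)
  totals <- tapply(areas$area_total, areas$charge, sum)
  top_charge <- as.integer(names(totals)[which.max(totals)])
  sel <- areas[areas$charge == top_charge, , drop = FALSE]
  res <- ms1_fold_change(
    sel$area_total[sel$sample_group == "bait"],
    sel$area_total[sel$sample_group == "control"],
    var_equal = var_equal, area_floor = area_floor
  )
  c(list(peptide = sel$peptide[1L], charge = top_charge), res,
    list(areas = sel))
}
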