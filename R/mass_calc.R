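# Monoisotopic mass arithmetic for peptides, precursors and b/y fragment
# ladders, including phospho neutral-loss bookkeeping. All constants are
# monoisotopic and fixed to six decimals; internal math never rounds —
# rounding happens only when comparing with values printed at instrument
# precision.

#' Monoisotopic constants used throughout the package
#'
#' Proton, water, phospho modification (+HPO3) and the H3PO4 neutral loss,
#' all in daltons (monoisotopic).
#' @format Named numeric vector.
#' @export
MASS_CONSTANTS <- c(
  proton = 1.007276,
  water = 18.010565,
  phospho = 79.96633,
  h3po4_loss = 97.976896
)

#' Monoisotopic residue masses
#'
#' Standard monoisotopic masses of the 20 canonical amino-acid residues
#' (Da), i.e. the mass each residue contributes inside a peptide chain.
#' @format Named numeric vector, names are one-letter residue codes.
#' @export
RESIDUE_MASSES <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931
)

# residues that can carry a phospho group
PHOSPHO_RESIDUES <- c("S", "T", "Y")

#' Construct a modification list
#'
#' @param position 1-based residue positions within the peptide.
#' @param delta_mass Monoisotopic mass shifts in Da. Defaults to the
#'   phospho shift (+79.96633) for every position.
#' @param name Modification names; `"phospho"` entries are validated to
#'   sit on S, T or Y.
#' @return A data.frame with columns `position`, `delta_mass`, `name`.
#' @export
modifications <- function(position, delta_mass = MASS_CONSTANTS[["phospho"]],
                          name = "phospho") {
  data.frame(
    position = as.integer(position),
    delta_mass = rep_len(delta_mass, length(position)),
    name = rep_len(name, length(position)),
    stringsAsFactors = FALSE
  )
}

validate_mods <- function(peptide, mods) {
  if (is.null(mods) || nrow(mods) == 0L) {
    return(modifications(integer(0)))
  }
  n <- nchar(peptide)
  residues <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  if (any(mods$position < 1L | mods$position > n)) {
    stop("modification position outside peptide", call. = FALSE)
  }
  is_phos <- mods$name == "phospho"
  bad <- which(is_phos & !(residues[mods$position] %in% PHOSPHO_RESIDUES))
  if (length(bad) > 0L) {
    stop(
      "phospho modification on residue '",
      residues[mods$position[bad[1L]]], "' at position ",
      mods$position[bad[1L]], " (allowed: S, T, Y)",
      call. = FALSE
    )
  }
  mods
}

residue_mass_vector <- function(peptide) {
  residues <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  unknown <- which(!(residues %in% names(RESIDUE_MASSES)))
  if (length(unknown) > 0L) {
    stop("unknown residue '", residues[unknown[1L]], "' at position ",
         unknown[1L], call. = FALSE)
  }
  unname(RESIDUE_MASSES[residues])
}

#' Monoisotopic mass of a peptide
#'
#' Sum of residue masses plus one water, plus any modification mass shifts.
#'
#' @param peptide Peptide sequence.
#' @param mods Optional modification table from [modifications()].
#' @return Neutral monoisotopic mass in Da.
#' @export
monoisotopic_mass <- function(peptide, mods = NULL) {
  masses <- residue_mass_vector(peptide)
  mods <- validate_mods(peptide, mods)
  sum(masses) + MASS_CONSTANTS[["water"]] + sum(mods$delta_mass)
}

#' Precursor m/z of a peptide ion
#'
#' @param neutral_mass Neutral monoisotopic mass in Da.
#' @param charge Positive integer charge state.
#' @return m/z in thomson: `(neutral_mass + charge * proton) / charge`.
#' @export
precursor_mz <- function(neutral_mass, charge) {
  if (charge < 1L) stop("charge must be >= 1", call. = FALSE)
  (neutral_mass + charge * MASS_CONSTANTS[["proton"]]) / charge
}

#' Singly charged b/y fragment ladder
#'
#' Computes the full singly protonated b and y ion series of a peptide, and
#' for every phospho-containing prefix/suffix also the H3PO4 (-97.976896 Da)
#' neutral-loss partner ion. Only b/y at charge 1+ are generated.
#'
#' @param peptide Peptide sequence of length >= 2.
#' @param mods Optional modification table from [modifications()].
#' @return A data.frame with columns `series` ("b"/"y"), `index` (1-based
#'   ladder position), `charge` (1), `mz`, `neutral_loss` (0 or 97.976896).
#' @export
fragment_series <- function(peptide, mods = NULL) {
  n <- nchar(peptide)
  if (n < 2L) stop("peptide must have length >= 2", call. = FALSE)
  masses <- residue_mass_vector(peptide)
  mods <- validate_mods(peptide, mods)
  delta <- numeric(n)
  delta[mods$position] <- delta[mods$position] + mods$delta_mass
  phospho_pos <- mods$position[mods$name == "phospho"]
  proton <- MASS_CONSTANTS[["proton"]]
  water <- MASS_CONSTANTS[["water"]]
  loss <- MASS_CONSTANTS[["h3po4_loss"]]

  idx <- seq_len(n - 1L)
  prefix <- cumsum(masses + delta)[idx]
  b <- data.frame(
    series = "b", index = idx, charge = 1L,
    mz = prefix + proton, neutral_loss = 0,
    stringsAsFactors = FALSE
  )
  suffix <- rev(cumsum(rev(masses + delta)))[n - idx + 1L]
  y <- data.frame(
    series = "y", index = idx, charge = 1L,
    mz = suffix + water + proton, neutral_loss = 0,
    stringsAsFactors = FALSE
  )
  out <- rbind(b, y)
  if (length(phospho_pos) > 0L) {
    b_has <- vapply(idx, function(i) any(phospho_pos <= i), logical(1L))
    y_has <- vapply(idx, function(j) any(phospho_pos > n - j), logical(1L))
    nl <- rbind(b[b_has, ], y[y_has, ])
    if (nrow(nl) > 0L) {
      nl$mz <- nl$mz - loss
      nl$neutral_loss <- loss
      out <- rbind(out, nl)
    }
  }
  rownames(out) <- NULL
  out
}

match_peaks <- function(theoretical_mz, spectrum, tol) {
  # nearest observed peak within tol for each theoretical m/z
  obs_mz <- spectrum$mz
  vapply(theoretical_mz, function(m) {
    d <- abs(obs_mz - m)
    i <- which.min(d)
    if (length(i) == 1L && d[i] <= tol) i else NA_integer_
  }, integer(1L))
}

#' Phosphosite localisation by neutral-loss ion pairs
#'
#' Scores each candidate phosphosite of a peptide by the number of distinct
#' site-determining b/y ions (including their -98 H3PO4 neutral-loss
#' partners) matched in the spectrum, and returns the best-supported site.
#' A site-determining ion is one whose theoretical m/z under the candidate
#' site differs from its m/z under every other candidate site by more than
#' the matching tolerance. Ties are reported as ambiguous, never resolved
#' silently.
#'
#' @param spectrum Data.frame with columns `mz`, `intensity`.
#' @param peptide Peptide sequence.
#' @param candidate_sites 1-based S/T/Y positions to consider; default all
#'   S/T/Y in the peptide.
#' @param tol Matching tolerance in Th (default 0.05).
#' @return A list with `site` (best-supported position, `NA` if ambiguous),
#'   `ambiguous` (logical), `scores` (per-site data.frame with matched and
#'   site-determining counts) and `matches` (the matched ion pairs of the
#'   best site).
#' @export
neutral_loss_support <- function(spectrum, peptide, candidate_sites = NULL,
                                 tol = 0.05) {
  residues <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  sty <- which(residues %in% PHOSPHO_RESIDUES)
  if (length(sty) == 0L) {
    stop("peptide has no S/T/Y residue to localise", call. = FALSE)
  }
  if (is.null(candidate_sites)) candidate_sites <- sty
  if (!all(candidate_sites %in% sty)) {
    stop("candidate_sites must be S/T/Y positions", call. = FALSE)
  }
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)

  ladders <- lapply(candidate_sites, function(p) {
    fragment_series(peptide, modifications(p))
  })
  names(ladders) <- as.character(candidate_sites)

  score_one <- function(k) {
    lad <- ladders[[k]]
    # site-determining: the ion's m/z (or its very existence) differs from
    # at least one other candidate ladder, so matching it carries
    # information about the site; ions shared by every candidate are
    # uninformative. With a single candidate every ion is determining.
    if (length(ladders) == 1L) {
      determining <- rep(TRUE, nrow(lad))
    } else {
      determining <- rep(FALSE, nrow(lad))
      for (j in seq_along(ladders)) {
        if (j == k) next
        other <- ladders[[j]]
        key <- paste(lad$series, lad$index, lad$neutral_loss)
        okey <- paste(other$series, other$index, other$neutral_loss)
        m <- match(key, okey)
        differs <- is.na(m) | abs(lad$mz - other$mz[m]) > tol
        determining <- determining | differs
      }
    }
    hit <- match_peaks(lad$mz, spectrum, tol)
    lad$matched <- !is.na(hit)
    lad$mz_observed <- ifelse(lad$matched, spectrum$mz[hit], NA_real_)
    lad$site_determining <- determining
    list(
      n_matched = sum(lad$matched),
      n_determining_matched = sum(lad$matched & determining),
      ladder = lad
    )
  }
  scored <- lapply(seq_along(ladders), score_one)
  scores <- data.frame(
    site = candidate_sites,
    n_matched = vapply(scored, `[[`, numeric(1L), "n_matched"),
    n_site_determining_matched =
      vapply(scored, `[[`, numeric(1L), "n_determining_matched")
  )
  best <- max(scores$n_site_determining_matched)
  winners <- scores$site[scores$n_site_determining_matched == best]
  ambiguous <- length(winners) > 1L
  best_k <- which(candidate_sites == winners[1L])
  matches <- scored[[best_k]]$ladder
  matches <- matches[matches$matched, c("series", "index", "mz",
                                        "mz_observed", "neutral_loss")]
  list(
    site = if (ambiguous) NA_integer_ else winners[1L],
    ambiguous = ambiguous,
    candidate_sites = winners,
    scores = scores,
    matches = matches
  )
}

#' Export an annotated fragment ladder to TSV
#'
#' @param matches Matched-ion table as returned in
#'   `neutral_loss_support()$matches`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotated_spectrum <- function(matches, path) {
  out <- data.frame(
    series = matches$series,
    index = matches$index,
    mz_theoretical = matches$mz,
    mz_observed = matches$mz_observed,
    delta = matches$mz_observed - matches$mz,
    neutral_loss = matches$neutral_loss
  )
  write_tsv(out, path)
  invisible(path)
}
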