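# Synthetic pulldown experiments: a random proteome with planted roles
# (bait, true interactors, contaminants, background), Poisson or
# negative-binomial spectral counts in a two-arm (control vs bait),
# 2 process x 3 technical replicate design, Gaussian-peak XICs for the
# M/M+1/M+2 precursor isotopes, and noisy b/y fragment spectra. Every
# generator is a pure function of its configuration: the same config gives
# byte-identical output.

#' Simulation configuration
#'
#' Defaults define the study conditions emulated throughout the test
#' suite: a two-arm pulldown, 2 process x 3 technical replicates per arm,
#' Poisson counts whose per-replicate mean is
#' `base_rate * (abundance / abundance_scale)^abundance_coupling`, with an
#' additional `enrichment_fold` multiplier in the bait arm for the bait
#' and the true interactors.
#'
#' @param seed Integer seed; recorded in every output file header.
#' @param n_proteins Proteome size (default 200).
#' @param n_true_interactors Planted true interactors (default 20).
#' @param n_contaminants Planted proteins carrying a removal-triggering
#'   attribute (contaminant-list membership, contaminant family, high
#'   reference abundance, or paralogy to an abundant protein; default 50).
#' @param bait_id Accession of the bait (default "BAIT001").
#' @param bait_gene Gene symbol of the bait (default "Gadd45a").
#' @param enrichment_fold Bait-arm enrichment of bait and true interactors
#'   (default 50).
#' @param base_rate Mean spectral counts per technical replicate for a
#'   background binder at the reference abundance scale (default 3).
#' @param abundance_coupling Exponent linking reference abundance to the
#'   background binding rate (default 0.5).
#' @param abundance_scale Reference abundance at which the background rate
#'   equals `base_rate` (default 1e-4, the abundance-filter threshold).
#' @param process_replicates,technical_replicates Replicate structure
#'   (defaults 2 and 3).
#' @param count_model `"poisson"` (default) or `"negative_binomial"`.
#' @param dispersion Negative-binomial size parameter is `1/dispersion`
#'   (default dispersion 0.3); ignored for Poisson.
#' @param decoy_rate Fraction of decoy PSMs appended (default 0.02).
#' @param min_peptide_len,max_peptide_len Observable peptide window used
#'   when distributing counts over peptides (defaults 7 and 35).
#' @param proline_rule Digestion proline rule (default `FALSE`).
#' @return A validated list of class `tapms_sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_proteins = 200L,
                              n_true_interactors = 20L,
                              n_contaminants = 50L,
                              bait_id = "BAIT001",
                              bait_gene = "Gadd45a",
                              enrichment_fold = 50,
                              base_rate = 3,
                              abundance_coupling = 0.5,
                              abundance_scale = 1e-4,
                              process_replicates = 2L,
                              technical_replicates = 3L,
                              count_model = c("poisson",
                                              "negative_binomial"),
                              dispersion = 0.3,
                              decoy_rate = 0.02,
                              min_peptide_len = 7L,
                              max_peptide_len = 35L,
                              proline_rule = FALSE) {
  count_model <- match.arg(count_model)
  config <- list(
    seed = as.integer(seed), n_proteins = as.integer(n_proteins),
    n_true_interactors = as.integer(n_true_interactors),
    n_contaminants = as.integer(n_contaminants),
    bait_id = bait_id, bait_gene = bait_gene,
    enrichment_fold = enrichment_fold, base_rate = base_rate,
    abundance_coupling = abundance_coupling,
    abundance_scale = abundance_scale,
    process_replicates = as.integer(process_replicates),
    technical_replicates = as.integer(technical_replicates),
    count_model = count_model, dispersion = dispersion,
    decoy_rate = decoy_rate,
    min_peptide_len = as.integer(min_peptide_len),
    max_peptide_len = as.integer(max_peptide_len),
    proline_rule = proline_rule
  )
  if (config$n_true_interactors + config$n_contaminants >
        config$n_proteins - 1L) {
    stop("role counts exceed the proteome size (minus the bait)",
         call. = FALSE)
  }
  if (config$enrichment_fold <= 0 || config$base_rate <= 0) {
    stop("rates must be positive", call. = FALSE)
  }
  class(config) <- "tapms_sim_config"
  config
}

# residue alphabet with ~11% combined K/R so tryptic digests look
# realistic (average peptide around 9 residues)
SIM_RESIDUE_FREQS <- c(
  A = 0.085, C = 0.015, D = 0.055, E = 0.065, F = 0.04, G = 0.07,
  H = 0.025, I = 0.055, K = 0.055, L = 0.095, M = 0.022, N = 0.04,
  P = 0.048, Q = 0.04, R = 0.055, S = 0.075, T = 0.055, V = 0.065,
  W = 0.012, Y = 0.033
)

random_protein_sequence <- function(len, config) {
  repeat {
    s <- paste(sample(names(SIM_RESIDUE_FREQS), len, replace = TRUE,
                      prob = SIM_RESIDUE_FREQS), collapse = "")
    n_obs <- count_theoretical_peptides(
      s, config$min_peptide_len, config$max_peptide_len,
      proline_rule = config$proline_rule
    )
    if (n_obs >= 1L) return(s)
  }
}

log_uniform <- function(n, lo, hi) {
  exp(stats::runif(n, log(lo), log(hi)))
}

#' Generate a synthetic proteome with planted roles
#'
#' Random sequences (100-1500 residues), a reference abundance table, a
#' gene-family map and a kinase list, constructed so that every filter in
#' the cascade has targets: planted contaminants are either on the
#' contaminant list, in a listed contaminant's family, more abundant than
#' the 0.01% threshold, or paralogs of an abundant protein. True
#' interactors are low-abundance; a fixed subset of them (13 when there
#' are at least 13) are labelled kinases.
#'
#' @param config A [simulation_config()].
#' @return List with `proteins` (protein table plus a `role` column),
#'   `reference` (gene_symbol, abundance), `family_map`, `kinases`
#'   (character vector), `contaminants` (character vector) and `truth`
#'   (per-protein role, abundance and expected per-replicate count rates
#'   in each arm).
#' @export
generate_proteome <- function(config = simulation_config()) {
  stopifnot(inherits(config, "tapms_sim_config"))
  set.seed(config$seed)
  n <- config$n_proteins
  n_int <- config$n_true_interactors
  n_con <- config$n_contaminants
  n_bg <- n - 1L - n_int - n_con

  protein_id <- c(config$bait_id, sprintf("P%04d", seq_len(n - 1L)))
  gene_symbol <- c(config$bait_gene, sprintf("G%04d", seq_len(n - 1L)))
  role <- c("bait", rep("true_interactor", n_int),
            rep("contaminant", n_con), rep("background", n_bg))

  lengths <- sample(100:1500, n, replace = TRUE)
  sequence <- vapply(lengths, random_protein_sequence, character(1L),
                     config = config)

  # contaminant substructure: listed / family-related / abundant / paralog
  n_listed <- max(1L, floor(0.4 * n_con))
  n_related <- floor(0.2 * n_con)
  n_abundant <- floor(0.3 * n_con)
  n_paralog <- n_con - n_listed - n_related - n_abundant
  con_kind <- rep(c("listed", "related", "abundant", "paralog"),
                  c(n_listed, n_related, n_abundant, n_paralog))

  is_int <- role == "true_interactor"
  is_con <- role == "contaminant"
  is_bg <- role == "background"
  kind <- rep(NA_character_, n)
  kind[is_con] <- con_kind

  abundance <- numeric(n)
  abundance[is_int] <- log_uniform(n_int, 5e-5, 1e-4)
  abundance[is_bg] <- log_uniform(n_bg, 1e-5, 1e-4)
  abundance[is_con & kind %in% c("listed", "related", "paralog")] <-
    log_uniform(sum(is_con & kind %in% c("listed", "related", "paralog")),
                1e-5, 1e-4)
  abundance[is_con & kind == "abundant"] <-
    log_uniform(sum(is_con & kind == "abundant"), 2e-4, 1e-2)
  abundance[role == "bait"] <- NA_real_  # transgene: absent from reference

  contaminants <- gene_symbol[is_con & kind == "listed"]
  # families: each related contaminant shares a family with one listed
  # contaminant; each paralog shares a family with one abundant protein
  related_sym <- gene_symbol[is_con & kind == "related"]
  related_anchor <- contaminants[
    ((seq_along(related_sym) - 1L) %% length(contaminants)) + 1L
  ]
  abundant_sym <- gene_symbol[is_con & kind == "abundant"]
  paralog_sym <- gene_symbol[is_con & kind == "paralog"]
  paralog_anchor <- abundant_sym[
    ((seq_along(paralog_sym) - 1L) %% max(1L, length(abundant_sym))) + 1L
  ]
  family_map <- unique(rbind(
    data.frame(gene_symbol = related_anchor,
               family_id = paste0("FAM_", related_anchor)),
    data.frame(gene_symbol = related_sym,
               family_id = paste0("FAM_", related_anchor)),
    data.frame(gene_symbol = paralog_anchor,
               family_id = paste0("FAM_", paralog_anchor)),
    data.frame(gene_symbol = paralog_sym,
               family_id = paste0("FAM_", paralog_anchor))
  ))
  rownames(family_map) <- NULL

  n_kin <- min(13L, n_int)
  kinases <- gene_symbol[is_int][seq_len(n_kin)]

  # expected per-technical-replicate count rates
  a0 <- config$abundance_scale
  bg_abund <- ifelse(is.na(abundance), a0, abundance)
  rate_control <- config$base_rate *
    (bg_abund / a0)^config$abundance_coupling
  specific <- role %in% c("bait", "true_interactor")
  rate_bait <- rate_control * ifelse(specific, config$enrichment_fold, 1)

  proteins <- data.frame(
    protein_id = protein_id, gene_symbol = gene_symbol,
    sequence = sequence,
    description = paste0("synthetic ", role,
                         ifelse(is.na(kind), "", paste0(" (", kind, ")"))),
    role = role, stringsAsFactors = FALSE
  )
  reference <- data.frame(
    gene_symbol = gene_symbol[!is.na(abundance)],
    abundance = abundance[!is.na(abundance)],
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    protein_id = protein_id, gene_symbol = gene_symbol, role = role,
    contaminant_kind = kind, abundance = abundance,
    rate_control = rate_control, rate_bait = rate_bait,
    stringsAsFactors = FALSE
  )
  list(proteins = proteins, reference = reference,
       family_map = family_map, kinases = kinases,
       contaminants = contaminants, truth = truth)
}

draw_counts <- function(n, mu, config) {
  if (config$count_model == "poisson") {
    stats::rpois(n, mu)
  } else {
    stats::rnbinom(n, size = 1 / config$dispersion, mu = mu)
  }
}

reverse_preserving_terminus <- function(peptide) {
  # pseudo-reversal: reverse all but the C-terminal residue so tryptic
  # decoys keep their terminal K/R
  n <- nchar(peptide)
  if (n <= 2L) return(peptide)
  body <- substr(peptide, 1L, n - 1L)
  paste0(paste(rev(strsplit(body, "", fixed = TRUE)[[1L]]), collapse = ""),
         substr(peptide, n, n))
}

#' Simulate a two-arm pulldown as a PSM table
#'
#' Per (arm, process replicate, technical replicate) cell, protein-level
#' PSM counts are drawn from the count model around the truth rates, then
#' distributed over the protein's observable tryptic peptides by a
#' uniform multinomial draw. Confidence values are drawn so that about
#' 95% of PSMs exceed 99; decoy PSMs with pseudo-reversed peptides are
#' appended at `decoy_rate`.
#'
#' @param proteome Output of [generate_proteome()].
#' @param config The same [simulation_config()].
#' @return A validated PSM data.frame.
#' @export
simulate_pulldown <- function(proteome, config = simulation_config()) {
  stopifnot(inherits(config, "tapms_sim_config"))
  set.seed(config$seed + 1000L)
  truth <- proteome$truth
  proteins <- proteome$proteins
  peptides <- lapply(proteins$sequence, function(s) {
    d <- tryptic_digest(s, missed_cleavages = 0L,
                        proline_rule = config$proline_rule)
    len <- nchar(d$peptide)
    d$peptide[len >= config$min_peptide_len & len <= config$max_peptide_len]
  })

  cells <- expand.grid(
    process_rep = seq_len(config$process_replicates),
    tech_rep = seq_len(config$technical_replicates),
    sample_group = c("control", "bait"),
    stringsAsFactors = FALSE
  )
  rows <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    mu <- if (cell$sample_group == "bait") truth$rate_bait else
      truth$rate_control
    counts <- draw_counts(nrow(truth), mu, config)
    idx <- rep(seq_len(nrow(truth)), counts)
    if (length(idx) == 0L) next
    pep <- vapply(idx, function(i) {
      p <- peptides[[i]]
      p[sample.int(length(p), 1L)]
    }, character(1L))
    high <- stats::runif(length(idx)) < 0.95
    confidence <- ifelse(high, stats::runif(length(idx), 99, 100),
                         stats::runif(length(idx), 90, 99))
    rows[[ci]] <- data.frame(
      sample_group = cell$sample_group,
      process_rep = cell$process_rep,
      tech_rep = cell$tech_rep,
      peptide = pep,
      mods = "",
      protein_id = truth$protein_id[idx],
      charge = sample(2:3, length(idx), replace = TRUE, prob = c(0.7, 0.3)),
      confidence = confidence,
      is_decoy = FALSE,
      stringsAsFactors = FALSE
    )
  }
  psms <- do.call(rbind, rows)

  n_decoy <- stats::rbinom(1L, nrow(psms), config$decoy_rate)
  if (n_decoy > 0L) {
    src <- psms[sample.int(nrow(psms), n_decoy, replace = TRUE), ,
                drop = FALSE]
    src$peptide <- vapply(src$peptide, reverse_preserving_terminus,
                          character(1L), USE.NAMES = FALSE)
    src$protein_id <- paste0("DECOY_", src$protein_id)
    src$confidence <- stats::runif(n_decoy, 90, 99.5)
    src$is_decoy <- TRUE
    psms <- rbind(psms, src)
  }
  psms$spectrum_id <- sprintf("scan%06d", seq_len(nrow(psms)))
  psms <- psms[, c("spectrum_id", "sample_group", "process_rep", "tech_rep",
                   "peptide", "mods", "protein_id", "charge", "confidence",
                   "is_decoy")]
  rownames(psms) <- NULL
  validate_psms(psms)
}

# relative intensities of the M, M+1, M+2 isotope channels; a fixed
# peptide-scale approximation (no averagine modelling)
ISOTOPE_WEIGHTS <- c("M" = 1.0, "M+1" = 0.55, "M+2" = 0.2)

#' Simulate extracted ion chromatograms for one peptide
#'
#' Gaussian elution peaks for the M/M+1/M+2 isotope channels in both arms
#' across technical replicates, with multiplicative log-normal noise of
#' coefficient of variation `noise_cv` applied independently per trace
#' (extraction/integration noise). With `noise_cv = 0` the bait/control
#' area ratio equals `true_fold_change` exactly.
#'
#' @param peptide Peptide sequence (labels the traces).
#' @param true_fold_change Bait/control abundance ratio (> 0).
#' @param noise_cv Replicate noise coefficient of variation (default 0.1).
#' @param config A [simulation_config()] (supplies seed and replicate
#'   structure).
#' @param charge Precursor charge label (default 2).
#' @param rt_center,rt_sigma Elution peak center and width in seconds
#'   (defaults 30 and 4).
#' @param base_amplitude Control-arm M-channel peak amplitude (default
#'   1e5).
#' @return Long-form XIC data.frame (`peptide`, `charge`, `channel`,
#'   `sample_group`, `tech_rep`, `rt`, `intensity`) on a 0-60 s grid.
#' @export
simulate_xic <- function(peptide, true_fold_change, noise_cv = 0.1,
                         config = simulation_config(), charge = 2L,
                         rt_center = 30, rt_sigma = 4,
                         base_amplitude = 1e5) {
  stopifnot(inherits(config, "tapms_sim_config"))
  if (true_fold_change <= 0) stop("fold change must be > 0", call. = FALSE)
  set.seed(config$seed + 2000L)
  rt <- seq(0, 60, by = 0.5)
  sdlog <- sqrt(log(1 + noise_cv^2))
  grid <- expand.grid(
    tech_rep = seq_len(config$technical_replicates),
    sample_group = c("control", "bait"),
    channel = names(ISOTOPE_WEIGHTS),
    stringsAsFactors = FALSE
  )
  out <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    arm_scale <- if (g$sample_group == "bait") true_fold_change else 1
    noise <- if (noise_cv > 0) {
      stats::rlnorm(1L, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else {
      1
    }
    amp <- base_amplitude * arm_scale * ISOTOPE_WEIGHTS[[g$channel]] * noise
    data.frame(
      peptide = peptide, charge = charge, channel = g$channel,
      sample_group = g$sample_group, tech_rep = g$tech_rep,
      rt = rt,
      intensity = amp * exp(-(rt - rt_center)^2 / (2 * rt_sigma^2)),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a centroided MS/MS spectrum for a peptide
#'
#' Places the full singly charged b/y ladder (plus -98 neutral-loss
#' partners for phosphopeptides) at the theoretical m/z with Gaussian
#' jitter, and adds uniform random noise peaks at about `1/snr` of the
#' signal intensity. y-ions whose N-terminal residue is proline are
#' boosted two-fold, mirroring the proline effect in collision-induced
#' dissociation.
#'
#' @param peptide Peptide sequence.
#' @param mods Optional modification table.
#' @param n_noise_peaks Number of noise peaks (default 50).
#' @param snr Signal-to-noise ratio (default 20).
#' @param config A [simulation_config()] (supplies the seed).
#' @param mz_jitter_sd Gaussian m/z jitter of signal peaks in Th (default
#'   0.005).
#' @return A spectrum data.frame (`mz`, `intensity`) with attributes
#'   `pepmass` (2+ precursor m/z) and `charge`.
#' @export
simulate_msms <- function(peptide, mods = NULL, n_noise_peaks = 50L,
                          snr = 20, config = simulation_config(),
                          mz_jitter_sd = 0.005) {
  stopifnot(inherits(config, "tapms_sim_config"))
  set.seed(config$seed + 3000L)
  ladder <- fragment_series(peptide, mods)
  signal <- stats::runif(nrow(ladder), 50, 100)
  residues <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  n <- length(residues)
  proline_y <- ladder$series == "y" &
    residues[n - ladder$index + 1L] == "P"
  signal[proline_y] <- signal[proline_y] * 2
  mz <- ladder$mz + stats::rnorm(nrow(ladder), 0, mz_jitter_sd)
  if (n_noise_peaks > 0L) {
    noise_mz <- stats::runif(n_noise_peaks, 100, max(ladder$mz) + 100)
    noise_int <- stats::runif(n_noise_peaks, 0, 100 / snr)
    mz <- c(mz, noise_mz)
    signal <- c(signal, noise_int)
  }
  sp <- spectrum(mz, signal)
  attr(sp, "pepmass") <- precursor_mz(monoisotopic_mass(peptide, mods), 2L)
  attr(sp, "charge") <- 2L
  sp
}
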