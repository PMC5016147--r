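# Configuration-driven end-to-end runner: protein inference ->
# spectral counting -> weighted counts -> enrichment ratio -> filter
# cascade -> kinase annotation, with all intermediates persisted and a
# manifest carrying the resolved configuration and a checksum per output.

#' Default pipeline configuration
#'
#' @param fasta,psms,contaminants,families,kinases,reference Input paths.
#' @param output_dir Output directory.
#' @param bait_id Accession of the bait protein.
#' @param enrichment_threshold Filter-1 threshold (default 30).
#' @param abundance_threshold Filter-3 fraction (default 1e-4).
#' @param min_confidence Peptide confidence cutoff (default 99).
#' @param min_peptides Distinct peptides per protein (default 2).
#' @param fdr Target-decoy q-value cutoff reported in the summary
#'   (default 0.01).
#' @param alpha MS1 t-test significance level (default 0.05).
#' @param ratio_mode `"weighted"` (default) or `"raw"` enrichment ratios.
#' @param min_peptide_len,max_peptide_len Observable-peptide window for
#'   theoretical counting (defaults 7, 35).
#' @param proline_rule Digestion proline rule (default `FALSE`).
#' @param overwrite Overwrite an existing non-empty output directory.
#' @return A named list (class `tapms_run_config`).
#' @export
run_config <- function(fasta, psms, contaminants, families, kinases,
                       reference, output_dir, bait_id,
                       enrichment_threshold = 30,
                       abundance_threshold = 1e-4,
                       min_confidence = 99, min_peptides = 2L,
                       fdr = 0.01, alpha = 0.05,
                       ratio_mode = c("weighted", "raw"),
                       min_peptide_len = 7L, max_peptide_len = 35L,
                       proline_rule = FALSE, overwrite = FALSE) {
  ratio_mode <- match.arg(ratio_mode)
  config <- list(
    fasta = fasta, psms = psms, contaminants = contaminants,
    families = families, kinases = kinases, reference = reference,
    output_dir = output_dir, bait_id = bait_id,
    enrichment_threshold = enrichment_threshold,
    abundance_threshold = abundance_threshold,
    min_confidence = min_confidence,
    min_peptides = as.integer(min_peptides),
    fdr = fdr, alpha = alpha, ratio_mode = ratio_mode,
    min_peptide_len = as.integer(min_peptide_len),
    max_peptide_len = as.integer(max_peptide_len),
    proline_rule = proline_rule, overwrite = overwrite
  )
  thresholds <- c(config$enrichment_threshold, config$abundance_threshold,
                  config$min_confidence, config$min_peptides, config$fdr,
                  config$alpha)
  if (any(thresholds <= 0)) {
    stop("all thresholds must be positive", call. = FALSE)
  }
  class(config) <- "tapms_run_config"
  config
}

#' Load a pipeline configuration from a YAML file
#'
#' Flat key-value YAML; relative paths are resolved against the file's
#' directory.
#'
#' @param path YAML config file.
#' @return A `tapms_run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (key in c("fasta", "psms", "contaminants", "families", "kinases",
                "reference", "output_dir")) {
    if (!is.null(raw[[key]]) && !grepl("^/", raw[[key]])) {
      raw[[key]] <- file.path(base, raw[[key]])
    }
  }
  do.call(run_config, raw)
}

check_resources <- function(config) {
  for (key in c("fasta", "psms", "contaminants", "families", "kinases",
                "reference")) {
    if (is.null(config[[key]]) || !file.exists(config[[key]])) {
      stop("missing resource '", key, "': ",
           config[[key]] %||% "(not set)", call. = FALSE)
    }
  }
  invisible(config)
}

#' Run the full pulldown analysis pipeline
#'
#' Executes protein inference, spectral counting, weighted counting,
#' enrichment ratios, the three-filter cascade and kinase annotation, and
#' persists every intermediate under `config$output_dir` together with a
#' machine-readable run summary (`summary.json`) and a manifest
#' (`manifest.json`) holding the resolved configuration and an MD5
#' checksum per output file.
#'
#' @param config A [run_config()] or path to a YAML file for
#'   [read_run_config()].
#' @return Invisibly, a list with `quant`, `decisions`, `tallies`,
#'   `candidates`, `kinase_fraction`, `inference`, `summary` and
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "tapms_run_config"))
  check_resources(config)
  out_dir <- config$output_dir
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0L &&
        !isTRUE(config$overwrite)) {
    stop("output directory not empty (use overwrite = TRUE): ", out_dir,
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  proteins <- read_fasta(config$fasta)
  psms <- read_psm_table(config$psms)
  contaminants <- read_gene_list(config$contaminants)
  family_map <- read_family_map(config$families)
  kinases <- read_gene_list(config$kinases)
  reference <- read_reference_abundance(config$reference)

  inference <- infer_proteins(psms, config$min_confidence,
                              config$min_peptides)
  accepted <- inference$accepted
  counts <- aggregate_spectral_counts(psms, config$min_confidence)
  counts <- counts[counts$protein_id %in% accepted, , drop = FALSE]

  theoretical <- data.frame(
    protein_id = proteins$protein_id,
    theoretical_peptides = vapply(
      proteins$sequence, count_theoretical_peptides, integer(1L),
      min_len = config$min_peptide_len, max_len = config$max_peptide_len,
      proline_rule = config$proline_rule, USE.NAMES = FALSE
    )
  )
  unknown <- setdiff(counts$protein_id, theoretical$protein_id)
  if (length(unknown) > 0L) {
    stop("PSMs reference proteins absent from the FASTA: ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  quant <- weighted_counts(counts, theoretical)
  quant <- enrichment_ratio(quant, mode = config$ratio_mode)
  quant$gene_symbol <-
    proteins$gene_symbol[match(quant$protein_id, proteins$protein_id)]

  cascade <- run_cascade(
    quant, contaminants, family_map, reference,
    bait_id = config$bait_id,
    enrichment_threshold = config$enrichment_threshold,
    abundance_threshold = config$abundance_threshold
  )
  annotated <- annotate_kinases(cascade$retained, kinases,
                                bait_id = config$bait_id)

  decoy_summary <- NULL
  if (any(psms$is_decoy)) {
    q <- target_decoy_fdr(psms$confidence, psms$is_decoy)
    decoy_summary <- list(
      n_decoys = sum(psms$is_decoy),
      n_psms_passing_fdr = sum(q <= config$fdr & !psms$is_decoy)
    )
  }

  paths <- c(
    inference = file.path(out_dir, "inference.tsv"),
    quant = file.path(out_dir, "quant.tsv"),
    decisions = file.path(out_dir, "filter_decisions.tsv"),
    candidates = file.path(out_dir, "candidates.tsv"),
    summary = file.path(out_dir, "summary.json")
  )
  write_tsv(inference$summary, paths[["inference"]])
  write_quant_table(quant, paths[["quant"]])
  write_tsv(cascade$decisions, paths[["decisions"]])
  cand <- annotated$candidates
  cand_cols <- intersect(
    c("protein_id", "gene_symbol", "sc_control", "sc_bait", "wsc_bait",
      "ratio", "reason", "is_kinase"),
    names(cand)
  )
  write_tsv(cand[, cand_cols, drop = FALSE], paths[["candidates"]])

  summary <- list(
    n_proteins_quantified = nrow(quant),
    n_accepted = length(accepted),
    n_single_peptide = length(inference$single_peptide),
    tallies = as.list(cascade$tallies),
    n_candidates = nrow(cand),
    n_kinases = annotated$n_kinases,
    kinase_fraction = annotated$kinase_fraction,
    decoy = decoy_summary
  )
  jsonlite::write_json(summary, paths[["summary"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  manifest <- list(
    tapms_version = tapms_version(),
    config = unclass(config),
    outputs = lapply(as.list(paths), function(p) {
      list(path = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(
    quant = quant, decisions = cascade$decisions,
    tallies = cascade$tallies, candidates = cand,
    kinase_fraction = annotated$kinase_fraction,
    inference = inference, summary = summary, manifest = manifest
  ))
}

#' Write a complete synthetic experiment to disk
#'
#' Generates a proteome and pulldown under the given simulation
#' configuration and writes exactly the files the pipeline consumes
#' (FASTA, PSM table, resource TSVs) plus the ground-truth table. The
#' seed is recorded in every TSV header.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return Invisibly, a named vector of the written paths.
#' @export
simulate_experiment <- function(config = simulation_config(), dir,
                                overwrite = FALSE) {
  if (dir.exists(dir) && length(dir(dir)) > 0L && !isTRUE(overwrite)) {
    stop("output directory not empty (use overwrite = TRUE): ", dir,
         call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  proteome <- generate_proteome(config)
  psms <- simulate_pulldown(proteome, config)
  seed_comment <- paste0("seed=", config$seed)
  paths <- c(
    fasta = file.path(dir, "proteome.fasta"),
    psms = file.path(dir, "psms.tsv"),
    contaminants = file.path(dir, "contaminants.tsv"),
    families = file.path(dir, "families.tsv"),
    kinases = file.path(dir, "kinases.tsv"),
    reference = file.path(dir, "reference_abundance.tsv"),
    truth = file.path(dir, "ground_truth.tsv")
  )
  write_fasta(proteome$proteins, paths[["fasta"]])
  write_psm_table(psms, paths[["psms"]], extra_comment = seed_comment)
  write_tsv(data.frame(gene_symbol = proteome$contaminants),
            paths[["contaminants"]], extra_comment = seed_comment)
  write_tsv(proteome$family_map, paths[["families"]],
            extra_comment = seed_comment)
  write_tsv(data.frame(gene_symbol = proteome$kinases),
            paths[["kinases"]], extra_comment = seed_comment)
  write_tsv(proteome$reference, paths[["reference"]],
            extra_comment = seed_comment)
  write_tsv(proteome$truth, paths[["truth"]], extra_comment = seed_comment)
  invisible(paths)
}

#' Synthetic quant table at the published composition of a Gadd45a screen
#'
#' A synthetic stand-in (not transcribed from any deposited dataset) for a
#' full-scale bait pulldown input table: 209 proteins in the bait sample of
#' which, by construction, 20 are control-detected with enrichment below
#' 30, 19 are listed affinity-purification contaminants, 17 share a family
#' with a listed contaminant, 78 are above the 0.01% abundance threshold
#' or paralogs of such proteins, and 75 (the bait plus 74 preys, 13 of
#' them kinases) survive the cascade. Used to exercise the cascade's
#' bookkeeping at a realistic scale.
#'
#' @return List with `quant`, `contaminants`, `family_map`, `reference`,
#'   `kinases`, `bait_id`.
#' @export
composition_fixture <- function() {
  n <- 209L
  bait_id <- "BAIT001"
  id <- c(bait_id, sprintf("P%03d", seq_len(n - 1L)))
  sym <- c("Gadd45a", sprintf("G%03d", seq_len(n - 1L)))
  role <- c("bait",
            rep("low_enrichment", 20L),
            rep("listed_contaminant", 19L),
            rep("contaminant_family", 17L),
            rep("abundant", 60L),
            rep("abundant_paralog", 18L),
            rep("retained", 74L))
  sc_control <- ifelse(role == "low_enrichment", 5L,
                       ifelse(role %in% c("abundant", "listed_contaminant"),
                              0L, 0L))
  sc_bait <- ifelse(role == "bait", 400L,
                    ifelse(role == "low_enrichment", 25L, 40L))
  theoretical <- rep(20L, n)
  quant <- weighted_counts(
    data.frame(protein_id = id, sc_control = sc_control,
               sc_bait = sc_bait, stringsAsFactors = FALSE),
    data.frame(protein_id = id, theoretical_peptides = theoretical)
  )
  quant <- enrichment_ratio(quant)
  quant$gene_symbol <- sym[match(quant$protein_id, id)]
  quant$role <- role[match(quant$protein_id, id)]

  contaminants <- sym[role == "listed_contaminant"]
  related <- sym[role == "contaminant_family"]
  anchor <- contaminants[((seq_along(related) - 1L) %%
                            length(contaminants)) + 1L]
  abundant <- sym[role == "abundant"]
  paralog <- sym[role == "abundant_paralog"]
  p_anchor <- abundant[((seq_along(paralog) - 1L) %% length(abundant)) + 1L]
  family_map <- unique(rbind(
    data.frame(gene_symbol = anchor, family_id = paste0("FAM_", anchor)),
    data.frame(gene_symbol = related, family_id = paste0("FAM_", anchor)),
    data.frame(gene_symbol = p_anchor,
               family_id = paste0("FAM_", p_anchor)),
    data.frame(gene_symbol = paralog, family_id = paste0("FAM_", p_anchor))
  ))
  reference <- data.frame(
    gene_symbol = c(abundant, sym[role == "retained"]),
    abundance = c(rep(5e-4, length(abundant)),
                  rep(1e-5, sum(role == "retained")))
  )
  kinases <- sym[role == "retained"][seq_len(13L)]
  list(quant = quant, contaminants = contaminants,
       family_map = family_map, reference = reference, kinases = kinases,
       bait_id = bait_id)
}
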