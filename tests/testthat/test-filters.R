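# fixture: a 10-protein quant table where 2 fail enrichment, 3 are
# contaminant-family, 1 is abundant, and 4 survive
toy_tables <- function() {
  quant <- data.frame(
    protein_id = sprintf("P%02d", 1:10),
    gene_symbol = c("HSPA8", "HSPA1B", "PSMA1", "ACTA1", "MEKK4", "MKK3",
                    "JAK1", "RIOK3", "LOW1", "LOW2"),
    sc_control = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 2L, 3L),
    sc_bait = c(50L, 40L, 30L, 60L, 80L, 20L, 15L, 10L, 10L, 12L),
    stringsAsFactors = FALSE
  )
  theo <- data.frame(protein_id = quant$protein_id,
                     theoretical_peptides = rep(10L, 10))
  quant <- enrichment_ratio(weighted_counts(quant[, 1:4], theo))
  quant$gene_symbol <- c("HSPA8", "HSPA1B", "PSMA1", "ACTA1", "MEKK4",
                         "MKK3", "JAK1", "RIOK3", "LOW1",
                         "LOW2")[match(quant$protein_id,
                                       sprintf("P%02d", 1:10))]
  list(
    quant = quant,
    contaminants = c("HSPA8", "PSMA1"),
    family_map = data.frame(
      gene_symbol = c("HSPA8", "HSPA1B", "ACTA1", "ACTB"),
      family_id = c("HSPA", "HSPA", "ACT", "ACT")
    ),
    reference = data.frame(
      gene_symbol = c("ACTB", "MEKK4", "MKK3", "JAK1"),
      abundance = c(2e-3, 1e-6, 1e-6, 1e-4)
    ),
    kinases = c("MEKK4", "MKK3", "JAK1", "RIOK3")
  )
}

test_that("filter 1 removes control-detected proteins strictly below the
           threshold", {
  quant <- data.frame(
    protein_id = c("A", "B", "C"),
    detected_in_control = c(TRUE, FALSE, TRUE),
    ratio = c(29.9, Inf, 30)
  )
  d <- filter_low_enrichment(quant, threshold = 30)
  expect_equal(d$stage,
               c("filter1_low_enrichment", "retained", "retained"))
})

test_that("filter 2 removes listed contaminants and their families", {
  tt <- toy_tables()
  d <- filter_contaminants(tt$quant, tt$contaminants, tt$family_map)
  stage <- d$stage[match(c("P01", "P02", "P03", "P05"), d$protein_id)]
  expect_equal(stage, c("filter2_contaminant", "filter2_contaminant",
                        "filter2_contaminant", "retained"))
  reason <- d$reason[match(c("P01", "P02"), d$protein_id)]
  expect_equal(reason, c("listed contaminant", "family of contaminant"))
  expect_equal(d$evidence[d$protein_id == "P02"], "HSPA")
})

test_that("filter 3 removes abundant proteins and paralogs, boundary
           retained, absent retained", {
  tt <- toy_tables()
  d <- filter_abundant(tt$quant, tt$reference, 1e-4, tt$family_map)
  # ACTA1 shares family ACT with abundant ACTB -> paralog removal
  expect_equal(d$stage[d$protein_id == "P04"], "filter3_abundant")
  expect_equal(d$reason[d$protein_id == "P04"],
               "paralog of abundant protein")
  # JAK1 at exactly 1e-4 is retained (strict > removal)
  expect_equal(d$stage[d$protein_id == "P07"], "retained")
  # RIOK3 absent from the reference: retained, flagged
  expect_equal(d$reason[d$protein_id == "P08"], "not in reference")
  # direct abundance removal
  d2 <- filter_abundant(
    data.frame(protein_id = "X", gene_symbol = "ABUND"),
    data.frame(gene_symbol = "ABUND", abundance = 2e-4), 1e-4, NULL
  )
  expect_equal(d2$stage, "filter3_abundant")
})

test_that("the cascade partitions its input with the expected tallies and
           is idempotent and order independent", {
  tt <- toy_tables()
  res <- run_cascade(tt$quant, tt$contaminants, tt$family_map,
                     tt$reference)
  expect_equal(unname(res$tallies[c("filter1_low_enrichment",
                                    "filter2_contaminant",
                                    "filter3_abundant")]),
               c(2L, 3L, 1L))
  expect_equal(unname(res$tallies[["retained"]]), 4L)
  expect_equal(sum(res$tallies), nrow(tt$quant))
  expect_setequal(res$retained$gene_symbol,
                  c("MEKK4", "MKK3", "JAK1", "RIOK3"))
  # every protein gets exactly one stage
  expect_equal(sort(res$decisions$protein_id), sort(tt$quant$protein_id))
  expect_true(all(res$decisions$stage %in%
                    c("retained", "filter1_low_enrichment",
                      "filter2_contaminant", "filter3_abundant")))
  # idempotence: re-running on the retained set removes nothing
  res2 <- run_cascade(res$retained[, names(tt$quant)], tt$contaminants,
                      tt$family_map, tt$reference)
  expect_equal(unname(res2$tallies[["retained"]]), nrow(res$retained))
  # order independence
  perm <- tt$quant[sample(nrow(tt$quant)), ]
  res3 <- run_cascade(perm, tt$contaminants, tt$family_map, tt$reference)
  m <- match(res$decisions$protein_id, res3$decisions$protein_id)
  expect_equal(res$decisions$stage, res3$decisions$stage[m])
  # empty input
  res0 <- run_cascade(tt$quant[0, ], tt$contaminants, tt$family_map,
                      tt$reference)
  expect_true(all(res0$tallies == 0L))
})

test_that("raising the enrichment threshold never rescues a removed
           protein", {
  tt <- toy_tables()
  lo <- filter_low_enrichment(tt$quant, threshold = 10)
  hi <- filter_low_enrichment(tt$quant, threshold = 50)
  removed_lo <- lo$protein_id[lo$stage != "retained"]
  removed_hi <- hi$protein_id[hi$stage != "retained"]
  expect_true(all(removed_lo %in% removed_hi))
})

test_that("the bait bypasses every filter", {
  tt <- toy_tables()
  quant <- tt$quant
  quant$gene_symbol[quant$protein_id == "P01"] <- "HSPA8"
  res <- run_cascade(quant, tt$contaminants, tt$family_map, tt$reference,
                     bait_id = "P01")
  expect_equal(res$decisions$stage[res$decisions$protein_id == "P01"],
               "retained")
  expect_equal(res$decisions$reason[res$decisions$protein_id == "P01"],
               "bait")
})

test_that("kinase annotation excludes the bait from both numerator and
           denominator", {
  cands <- data.frame(
    protein_id = c("B0", sprintf("P%02d", 1:4)),
    gene_symbol = c("Gadd45a", "MEKK4", "MKK3", "OTHER1", "OTHER2")
  )
  ann <- annotate_kinases(cands, c("MEKK4", "MKK3", "Gadd45a"),
                          bait_id = "B0")
  expect_equal(ann$n_non_bait, 4L)
  expect_equal(ann$n_kinases, 2L)
  expect_equal(ann$kinase_fraction, 0.5)
  expect_false(ann$candidates$is_kinase[1])

  none <- annotate_kinases(cands, character(0), bait_id = "B0")
  expect_equal(none$kinase_fraction, 0)
  all_k <- annotate_kinases(cands[-1, ],
                            cands$gene_symbol[-1], bait_id = "B0")
  expect_equal(all_k$kinase_fraction, 1)
})

test_that("the cascade reproduces the published-scale composition:
           tallies 20/36/78, 75 retained, 13 kinases of 74", {
  fx <- composition_fixture()
  res <- run_cascade(fx$quant, fx$contaminants, fx$family_map,
                     fx$reference, bait_id = fx$bait_id)
  expect_equal(unname(res$tallies[c("filter1_low_enrichment",
                                    "filter2_contaminant",
                                    "filter3_abundant")]),
               c(20L, 36L, 78L))
  expect_equal(unname(res$tallies[["retained"]]), 75L)
  ann <- annotate_kinases(res$retained, fx$kinases, bait_id = fx$bait_id)
  expect_equal(ann$n_non_bait, 74L)
  expect_equal(ann$n_kinases, 13L)
  expect_equal(round(100 * ann$kinase_fraction), 18)
})
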