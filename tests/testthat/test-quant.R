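make_psms <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, rows)
  df$spectrum_id <- sprintf("s%03d", seq_len(nrow(df)))
  df
}

test_that("spectral counts tally PSMs per arm above the confidence cutoff
           and exclude decoys", {
  psms <- make_psms(
    psm("P1", group = "bait", proc = 1), psm("P1", group = "bait", proc = 2),
    psm("P1", group = "bait", proc = 2, tech = 2),
    psm("P1", group = "control"),
    psm("P1", group = "bait", confidence = 98.9),     # below cutoff
    psm("P1", group = "bait", decoy = TRUE),          # decoy
    psm("P2", group = "bait")
  )
  counts <- aggregate_spectral_counts(psms, min_confidence = 99)
  expect_equal(counts$sc_bait[counts$protein_id == "P1"], 3L)
  expect_equal(counts$sc_control[counts$protein_id == "P1"], 1L)
  expect_equal(counts$sc_bait[counts$protein_id == "P2"], 1L)

  # order invariance
  shuffled <- psms[sample(nrow(psms)), ]
  expect_equal(aggregate_spectral_counts(shuffled, 99), counts)

  # additivity over disjoint batches
  half <- nrow(psms) %/% 2
  a <- aggregate_spectral_counts(psms[1:half, ], 99)
  b <- aggregate_spectral_counts(psms[(half + 1):nrow(psms), ], 99)
  merged <- merge(a, b, by = "protein_id", all = TRUE)
  merged[is.na(merged)] <- 0
  expect_equal(
    counts$sc_bait,
    (merged$sc_bait.x + merged$sc_bait.y)[match(counts$protein_id,
                                                merged$protein_id)]
  )

  bad <- psms
  bad$sample_group[1] <- "mock"
  expect_error(aggregate_spectral_counts(bad, 99), "mock")
})

test_that("weighted counts divide by theoretical peptides and flag
           undefined rows", {
  counts <- data.frame(protein_id = c("P1", "P2", "P3"),
                       sc_control = c(0L, 2L, 1L),
                       sc_bait = c(10L, 20L, 4L))
  theo <- data.frame(protein_id = c("P1", "P2", "P3"),
                     theoretical_peptides = c(20L, 100L, 0L))
  q <- weighted_counts(counts, theo)
  expect_equal(q$wsc_bait[1], 0.5)
  expect_equal(q$wsc_bait[2], 0.2)
  expect_true(is.na(q$wsc_bait[3]) && !q$wsc_defined[3])
  expect_equal(q$detected_in_control, c(FALSE, TRUE, TRUE))
  # doubling the theoretical count halves the weighted count
  theo2 <- transform(theo, theoretical_peptides = theoretical_peptides * 2L)
  q2 <- weighted_counts(counts, theo2)
  expect_equal(q2$wsc_bait[1:2], q$wsc_bait[1:2] / 2)
  # a small protein with sc 10/T 10 outranks a large one with sc 20/T 100
  expect_gt(10 / 10, q$wsc_bait[2])
})

test_that("enrichment ratios honour boundary and infinity semantics", {
  counts <- data.frame(protein_id = c("A", "B", "C", "D"),
                       sc_control = c(1L, 0L, 1L, 0L),
                       sc_bait = c(30L, 5L, 29L, 0L))
  theo <- data.frame(protein_id = counts$protein_id,
                     theoretical_peptides = rep(1L, 4))
  q <- enrichment_ratio(weighted_counts(counts, theo))
  ratio <- q$ratio[match(c("A", "B", "C", "D"), q$protein_id)]
  expect_equal(ratio[1], 30)
  expect_equal(ratio[2], Inf)
  expect_equal(ratio[3], 29)
  expect_true(is.na(ratio[4]))
  expect_false(q$ratio_defined[q$protein_id == "D"])

  # pseudocount keeps ratios finite and converges as c -> 0
  qc <- enrichment_ratio(weighted_counts(counts, theo), pseudocount = 1e-8)
  expect_true(all(is.finite(qc$ratio[qc$ratio_defined])))
  expect_equal(qc$ratio[qc$protein_id == "A"], 30, tolerance = 1e-6)
  # raw mode agrees here since all theoretical counts are 1
  qr <- enrichment_ratio(weighted_counts(counts, theo), mode = "raw")
  expect_equal(qr$ratio, q$ratio)
})

test_that("XIC areas integrate trapezoidally with window interpolation", {
  rt <- seq(0, 10, by = 0.5)
  expect_equal(xic_peak_area(rt, rep(100, length(rt))), 1000)
  expect_equal(xic_peak_area(rt, rep(0, length(rt))), 0)

  # Gaussian peak vs closed form A * sigma * sqrt(2*pi)
  a <- 500; sigma <- 2; center <- 30
  rt <- seq(center - 5 * sigma, center + 5 * sigma, by = 0.1)
  area <- xic_peak_area(rt, a * exp(-(rt - center)^2 / (2 * sigma^2)))
  expect_equal(area, a * sigma * sqrt(2 * pi), tolerance = 0.01)

  # additive over adjacent windows; invariant to collinear insertions
  rt <- seq(0, 20, by = 1)
  y <- 5 + rt
  whole <- xic_peak_area(rt, y)
  expect_equal(
    xic_peak_area(rt, y, c(0, 7.3)) + xic_peak_area(rt, y, c(7.3, 20)),
    whole, tolerance = 1e-9
  )
  rt2 <- sort(c(rt, 3.5, 11.25))
  expect_equal(xic_peak_area(rt2, 5 + rt2), whole, tolerance = 1e-9)

  expect_error(xic_peak_area(rt, y, c(30, 40)), "overlap")
  expect_error(xic_peak_area(c(1, 1, 2), c(0, 0, 0)), "increasing")
})

test_that("MS1 fold change and Welch test match the textbook oracle", {
  res <- ms1_fold_change(c(310, 300, 320), c(10, 10, 10))
  expect_equal(res$fold_change, 31, tolerance = 1e-9)
  expect_lt(res$p, 0.05)

  # identical vectors: fold change 1, p = 1
  null <- ms1_fold_change(c(100, 100, 100), c(100, 100, 100))
  expect_equal(null$fold_change, 1)
  expect_equal(null$p, 1)

  # swapping arms inverts the fold change and preserves p
  set.seed(21)
  b <- exp(rnorm(3, 5, 0.2)); ct <- exp(rnorm(3, 4, 0.2))
  fwd <- ms1_fold_change(b, ct)
  rev <- ms1_fold_change(ct, b)
  expect_equal(fwd$fold_change, 1 / rev$fold_change, tolerance = 1e-12)
  expect_equal(fwd$p, rev$p, tolerance = 1e-12)

  expect_error(ms1_fold_change(c(1, 0), c(1, 1)), "floor")
  expect_equal(ms1_fold_change(c(1, 0), c(1, 1),
                               area_floor = 0.5)$n_bait, 2L)

  # 100 random instances against the independent Welch formula
  set.seed(22)
  for (i in 1:100) {
    x <- exp(rnorm(sample(3:6, 1), 6, 0.5))
    y <- exp(rnorm(sample(3:6, 1), 5, 0.8))
    got <- ms1_fold_change(x, y)
    want <- oracle_welch(log(x), log(y))
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
})

test_that("ms1_quantify picks the most intense precursor charge state", {
  cfg <- simulation_config(seed = 5)
  x2 <- simulate_xic("ELVISLIVESK", 31, noise_cv = 0, config = cfg,
                     charge = 2, base_amplitude = 1e5)
  x3 <- simulate_xic("ELVISLIVESK", 31, noise_cv = 0, config = cfg,
                     charge = 3, base_amplitude = 2e4)
  res <- ms1_quantify(rbind(x2, x3))
  expect_equal(res$charge, 2L)
  expect_equal(res$fold_change, 31, tolerance = 1e-6)
})
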