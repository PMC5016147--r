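#!/usr/bin/env Rscript
# MS1 extracted-ion-chromatogram quantification of a representative
# peptide: integrate Gaussian elution peaks for the M/M+1/M+2 precursor
# isotopes per technical replicate, compute the bait/control fold change
# with a two-tailed Welch t-test on log areas, and assess recovery of a
# 31-fold enrichment under replicate noise.

suppressPackageStartupMessages(library(tapms))

pep <- "TINDQDLFLYTAR"
cat(sprintf("Peptide %s, precursor m/z (2+): %.2f\n", pep,
            precursor_mz(monoisotopic_mass(pep), 2)))

x0 <- simulate_xic(pep, 31, noise_cv = 0,
                   config = simulation_config(seed = 1))
r0 <- ms1_quantify(x0)
cat(sprintf("Noiseless recovery: fold change %.4f\n", r0$fold_change))

x <- simulate_xic(pep, 31, noise_cv = 0.1,
                  config = simulation_config(seed = 1))
r <- ms1_quantify(x)
cat(sprintf("One noisy draw (cv 0.1): fold change %.2f, p = %.2g\n",
            r$fold_change, r$p))

n_mc <- 200L
mc <- t(vapply(seq_len(n_mc), function(s) {
  xi <- simulate_xic(pep, 31, noise_cv = 0.1,
                     config = simulation_config(seed = s))
  ri <- ms1_quantify(xi)
  c(fold_change = ri$fold_change, p = ri$p)
}, numeric(2)))
ok <- abs(mc[, "fold_change"] - 31) / 31 <= 0.15 & mc[, "p"] < 0.05
cat(sprintf(
  "Monte Carlo (%d seeds): median fold change %.2f; %.1f%% within 15%% of 31 with p < 0.05\n",
  n_mc, stats::median(mc[, "fold_change"]), 100 * mean(ok)))

dir.create("results", showWarnings = FALSE)
out <- data.frame(seed = seq_len(n_mc), mc, within_15pct_significant = ok)
utils::write.table(out, file.path("results", "ms1_recovery.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("Wrote results/ms1_recovery.tsv\n")
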