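#!/usr/bin/env Rscript
# Score the pipeline's candidate list against the simulation ground
# truth: what fraction of planted true interactors was retained, and how
# many nonspecific proteins slipped through.

suppressPackageStartupMessages(library(tapms))

truth <- utils::read.delim(file.path("results", "experiment",
                                     "ground_truth.tsv"),
                           comment.char = "#")
cand <- utils::read.delim(file.path("results", "pipeline",
                                    "candidates.tsv"),
                          comment.char = "#")

candidates <- setdiff(cand$protein_id, "BAIT001")
by_role <- split(truth$protein_id[truth$role != "bait"],
                 truth$role[truth$role != "bait"])
summary <- do.call(rbind, lapply(names(by_role), function(role) {
  ids <- by_role[[role]]
  data.frame(role = role, n = length(ids),
             retained = sum(ids %in% candidates),
             retained_percent = 100 * mean(ids %in% candidates))
}))
print(summary, row.names = FALSE)

interactors <- truth$protein_id[truth$role == "true_interactor"]
others <- truth$protein_id[!(truth$role %in% c("true_interactor", "bait"))]
cat(sprintf("\nTrue-interactor recovery: %.1f%%\n",
            100 * mean(interactors %in% candidates)))
cat(sprintf("Nonspecific retention:    %.2f%%\n",
            100 * mean(others %in% candidates)))

dir.create("results", showWarnings = FALSE)
utils::write.table(summary, file.path("results", "recovery.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("Wrote results/recovery.tsv\n")
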