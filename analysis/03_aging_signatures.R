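#!/usr/bin/env Rscript
# Aging signatures: per-tissue Spearman correlation of every miRNA with
# age, classification into global / local / non-aging, and the nonlinear
# fold-change deregulation analysis against the 3-month baseline with
# Welch t-tests and per-(tissue, timepoint) BH correction. Compares the
# calls against the planted ground truth.

suppressPackageStartupMessages(library(ncatlas))

out <- "results/aging"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
th <- nc_thresholds()

cm <- read_count_matrix("results/filtering/filtered_counts.tsv",
                        "results/filtering/filtered_samples.tsv")
truth <- utils::read.delim("results/cohorts/aging_truth.tsv")

corr <- age_correlation_table(cm, th)
calls <- classify_aging(corr, th)
utils::write.table(corr, file.path(out, "age_correlations.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(calls, file.path(out, "aging_calls.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

tg <- truth$feature_id[truth$label == "global"]
got <- calls$feature_id[grepl("^global", calls$label)]
cat(sprintf("global aging calls: %d (%d planted; sensitivity %.2f, %d false)\n",
            length(got), length(tg), mean(tg %in% got),
            length(setdiff(got, tg))))
cat(sprintf("local aging calls: %d (%d planted)\n",
            sum(calls$label == "local"), sum(truth$label == "local")))

## deregulation vs the 3-month baseline, all tissues
recs <- do.call(rbind, lapply(unique(cm$samples$tissue), function(t) {
  foldchange_table(cm, t, th)
}))
utils::write.table(recs, file.path(out, "deregulation.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
counts <- deregulated_counts(recs)
utils::write.table(data.frame(tissue = rownames(counts), counts,
                              check.names = FALSE),
                   file.path(out, "deregulated_counts.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("deregulated records per tissue x timepoint:\n")
print(counts)
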