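#!/usr/bin/env Rscript
# Heterochronic parabiosis analysis: the same QC and abundance filters as
# the aging cohort, then per-tissue REJ / ACC / AGE fold changes with
# Welch t-tests, classification into the six deregulation comparison
# groups, and per-feature reversal summaries (z-score effect sizes) for
# the planted reversible miRNAs.

suppressPackageStartupMessages(library(ncatlas))

out <- "results/parabiosis"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
th <- nc_thresholds()

ann <- utils::read.delim("results/cohorts/annotation.tsv")
parab <- read_count_matrix("results/cohorts/parabiosis_counts.tsv",
                           "results/cohorts/parabiosis_samples.tsv")
aging <- read_count_matrix("results/filtering/filtered_counts.tsv",
                           "results/filtering/filtered_samples.tsv")
truth <- utils::read.delim("results/cohorts/parabiosis_truth.tsv")

parab <- filter_abundant_global(
  filter_pirna_prepachytene(qc_exclude_samples(parab, th), ann), th)
cat(sprintf("parabiosis matrix after filters: %d features x %d samples\n",
            nrow(parab$counts), ncol(parab$counts)))

effects <- do.call(rbind, lapply(unique(parab$samples$tissue), function(t) {
  parabiosis_effects(parab, aging, t, th)
}))
utils::write.table(effects, file.path(out, "effects.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

gc <- parabiosis_group_counts(effects)
utils::write.table(data.frame(tissue = rownames(gc), gc, check.names = FALSE),
                   file.path(out, "group_counts.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("comparison-group counts per tissue:\n")
print(gc)

rev_f <- intersect(truth$feature_id[truth$reversible],
                   rownames(parab$counts))
rej_groups <- c("REJ_up_AGE_down", "REJ_down_AGE_up")
sens <- mean(effects$group[effects$feature_id %in% rev_f] %in% rej_groups)
cat(sprintf("planted reversible miRNAs in REJ-opposite-AGE groups: %.2f\n",
            sens))

summaries <- do.call(rbind, lapply(rev_f[seq_len(min(5, length(rev_f)))],
                                   function(f) {
  reversal_summary(parab, f, "liver")
}))
utils::write.table(summaries, file.path(out, "reversal_summaries.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("liver reversal effect sizes (first planted reversible miRNAs):\n")
print(summaries[, c("feature_id", "effect_rej", "effect_acc",
                    "rej_to_acc_ratio")])
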