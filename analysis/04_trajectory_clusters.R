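#!/usr/bin/env Rscript
# Cross-organ trajectory clustering: z-score each miRNA's mean-per-
# timepoint trajectory in every tissue where it is expressed, choose the
# cluster number from the minimum-centroid-distance curve, run fuzzy
# c-means, and label tissue-specific clusters (>= 30% of members from one
# tissue). The planted global aging miRNAs should land in common
# cross-tissue clusters; tissue-local ones drive the specific clusters.

suppressPackageStartupMessages(library(ncatlas))

out <- "results/clustering"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
th <- nc_thresholds()
seed <- 42

cm <- read_count_matrix("results/filtering/filtered_counts.tsv",
                        "results/filtering/filtered_samples.tsv")
truth <- utils::read.delim("results/cohorts/aging_truth.tsv")

## miRNAs expressed (post local filter) in every tissue
tissues <- unique(cm$samples$tissue)
common <- Reduce(intersect, lapply(tissues, function(t) {
  rownames(filter_abundant_local(cm, t, th)$counts)
}))
ts <- zscore_trajectories(cm, features = common)
cat(sprintf("%d trajectories (%d features x %d tissues grid)\n",
            nrow(ts$matrix), length(common), length(tissues)))

sel <- select_c(ts, c_range = th$c_range, seeds = 1:2)
cat(sprintf("minimum-centroid-distance rule selects c = %d%s\n", sel$c_opt,
            if (sel$low_confidence) " (low confidence)" else ""))
utils::write.table(sel$dmin_curve, file.path(out, "dmin_curve.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

fit <- fuzzy_cmeans(ts, sel$c_opt, seed = seed)
assign <- cbind(ts$keys, cluster = fit$hard_labels,
                membership = fit$memberships[cbind(seq_len(nrow(ts$keys)),
                                                   fit$hard_labels)])
utils::write.table(assign, file.path(out, "cluster_assignments.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

spec <- tissue_specificity(fit, ts$keys, th)
utils::write.table(spec, file.path(out, "cluster_specificity.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("%d of %d clusters are tissue-specific (>= %.0f%% one tissue)\n",
            sum(spec$is_specific), nrow(spec),
            100 * th$tissue_specific_frac))

tg <- truth$feature_id[truth$label == "global"]
cat(sprintf("cross-tissue co-clustering of planted global miRNAs: %.2f\n",
            cross_tissue_coclustering(fit, ts$keys, tg)))
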