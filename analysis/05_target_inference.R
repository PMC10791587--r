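#!/usr/bin/env Rscript
# miRNA-mRNA target inference for the global aging miRNAs: inverse
# Spearman correlation (rho < -0.4, P < 0.05) supported in at least two
# tissues, a mirrored positive-correlation control set, conserved
# binding-site enrichment (per site type and any), and target-set
# overlaps across the miRNAs.

suppressPackageStartupMessages(library(ncatlas))

out <- "results/targets"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
th <- nc_thresholds()

mirna_cm <- read_count_matrix("results/filtering/filtered_counts.tsv",
                              "results/filtering/filtered_samples.tsv")
mrna_cm <- read_count_matrix("results/cohorts/mrna_counts.tsv",
                             "results/cohorts/mrna_samples.tsv")
sites <- read_site_table("results/cohorts/binding_sites.tsv")
calls <- utils::read.delim("results/aging/aging_calls.tsv")
target_truth <- utils::read.delim("results/cohorts/target_truth.tsv")

glob <- calls$feature_id[grepl("^global", calls$label)]
cat(sprintf("testing %d global aging miRNAs against %d genes\n",
            length(glob), nrow(mrna_cm$counts)))

case <- call_targets(mirna_cm, mrna_cm, glob, th)
ctrl <- control_targets(mirna_cm, mrna_cm, glob, th)
utils::write.table(case$pairs, file.path(out, "target_pairs.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(ctrl$pairs, file.path(out, "control_pairs.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("inverse pairs: %d; positive-control pairs: %d\n",
            nrow(case$pairs), nrow(ctrl$pairs)))

tt <- target_truth[target_truth$role == "target", ]
sens <- mean(paste(tt$mirna, tt$gene) %in%
               paste(case$pairs$mirna, case$pairs$gene))
cat(sprintf("planted targets recovered: %.2f\n", sens))

enr <- site_enrichment(case$pairs, ctrl$pairs, sites)
utils::write.table(enr, file.path(out, "site_enrichment.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
for (i in seq_len(nrow(enr))) {
  cat(sprintf("%-8s %5.2f%% vs %5.2f%% -> fold %.1f, Fisher p %.2g\n",
              enr$site_type[i], enr$frac_case[i], enr$frac_ctrl[i],
              enr$fold[i], enr$p_fisher[i]))
}

ov <- target_set_overlaps(case$pairs)
utils::write.table(ov, file.path(out, "target_overlaps.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("%d Venn regions over %d miRNA target sets\n", nrow(ov),
            length(unique(case$pairs$mirna))))
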