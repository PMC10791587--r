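#!/usr/bin/env Rscript
# Generate the synthetic study cohorts: a 6-tissue x 10-timepoint aging
# cohort with planted global and tissue-local aging miRNAs, the paired
# mRNA matrix with planted inverse-correlated targets and enriched
# conserved binding sites, and a 4-group heterochronic parabiosis cohort
# with planted partial reversal. Writes the matrices, sample sheets,
# annotation and ground truth under results/cohorts/.

suppressPackageStartupMessages(library(ncatlas))

out <- "results/cohorts"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 42

design <- sim_design(seed = seed)
sim <- simulate_aging_cohort(design)
write_count_matrix(sim$cm, file.path(out, "aging_counts.tsv"),
                   file.path(out, "aging_samples.tsv"))
utils::write.table(sim$annotation, file.path(out, "annotation.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(sim$truth, file.path(out, "aging_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

mr <- simulate_mrna_partner(sim)
write_count_matrix(mr$cm, file.path(out, "mrna_counts.tsv"),
                   file.path(out, "mrna_samples.tsv"))
utils::write.table(mr$sites, file.path(out, "binding_sites.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(mr$truth, file.path(out, "target_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

pb <- simulate_parabiosis(sim)
write_count_matrix(pb$cm, file.path(out, "parabiosis_counts.tsv"),
                   file.path(out, "parabiosis_samples.tsv"))
utils::write.table(pb$truth, file.path(out, "parabiosis_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("aging cohort: %d features x %d samples (%d tissues)\n",
            nrow(sim$cm$counts), ncol(sim$cm$counts), design$n_tissues))
cat(sprintf("planted: %d global, %d local aging miRNAs\n",
            sum(sim$truth$label == "global"),
            sum(sim$truth$label == "local")))
cat(sprintf("mRNA partner: %d genes, %d binding-site rows\n",
            nrow(mr$cm$counts), nrow(mr$sites)))
cat(sprintf("parabiosis cohort: %d samples in groups %s\n",
            ncol(pb$cm$counts),
            paste(unique(pb$cm$samples$group), collapse = "/")))
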