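# Synthetic multi-organ cohort generator. Counts are negative-binomial with
# log-normal library sizes; aging features carry monotone log-linear mean
# trends; parabiosis group means interpolate linearly (on the rpmm scale)
# between the planted young and aged means. Every generator returns its
# ground truth so downstream stages have a recoverable answer.

TISSUE_POOL <- c("brain", "liver", "BAT", "kidney", "lung", "limb_muscle",
                 "heart", "spleen", "bone", "marrow", "skin", "pancreas",
                 "GAT", "MAT", "SCAT", "intestine")

#' Simulation design
#'
#' Defaults describe the desk-scale study: 6 tissues x 10 timepoints
#' (1..27 months) x 4 replicates, 20 planted global aging miRNAs (shared
#' sign across all tissues), 5 tissue-exclusive local aging miRNAs per
#' tissue, and a rare-piRNA background that the abundance filter should
#' remove. A 16-tissue full-scale mode is available via `n_tissues = 16`.
#'
#' @param n_tissues number of tissues (2..16).
#' @param timepoints ages in months.
#' @param reps_per_tp replicates per tissue and timepoint.
#' @param n_features_per_class named integer vector, features per RNA class.
#' @param n_global_aging planted global aging miRNAs (planted in all
#'   tissues with one sign per feature).
#' @param n_local_aging_per_tissue planted tissue-exclusive aging miRNAs.
#' @param effect_slope planted trend amplitude, log2 units across the whole
#'   lifespan.
#' @param nb_dispersion negative-binomial dispersion (0 = Poisson).
#' @param libsize_lognorm `c(meanlog, sdlog)` of per-sample library size.
#' @param n_targets_per_global_mirna planted inverse-correlated target
#'   genes per global miRNA.
#' @param target_beta coupling strength (log2 gene units per standardized
#'   miRNA log2 rpmm).
#' @param conserved_enrichment odds multiplier for conserved binding sites
#'   on true-target pairs relative to random pairs.
#' @param parabiosis_reversal_frac fraction of the aged-to-young mean
#'   difference restored in heterochronic aged (HA) mice, rpmm scale.
#' @param parabiosis_accel_frac fraction of the young-to-aged difference
#'   imposed on heterochronic young (HY) mice.
#' @param parab_reps replicates per parabiosis group.
#' @param seed RNG seed; all generators are deterministic under it.
#' @return list of class `sim_design`.
#' @export
sim_design <- function(n_tissues = 6,
                       timepoints = c(1, 3, 6, 9, 12, 15, 18, 21, 24, 27),
                       reps_per_tp = 4,
                       n_features_per_class = c(miRNA = 200, piRNA = 60,
                                                lncRNA = 15, snoRNA = 15,
                                                snRNA = 10, tRNA = 10,
                                                rRNA = 5, scaRNA = 5),
                       n_global_aging = 20,
                       n_local_aging_per_tissue = 5,
                       effect_slope = 1.5,
                       nb_dispersion = 0.1,
                       libsize_lognorm = c(log(5e6), 0.2),
                       n_targets_per_global_mirna = 3,
                       target_beta = 1,
                       conserved_enrichment = 5,
                       parabiosis_reversal_frac = 0.8,
                       parabiosis_accel_frac = 0.2,
                       parab_reps = 7,
                       seed = 1) {
  d <- as.list(environment())
  if (d$n_tissues < 2 && d$n_global_aging > 0) {
    stop("global aging features require at least 2 tissues")
  }
  if (d$n_tissues > length(TISSUE_POOL)) {
    stop("at most ", length(TISSUE_POOL), " tissues supported")
  }
  if (d$parabiosis_reversal_frac < 0 || d$parabiosis_reversal_frac > 1) {
    stop("parabiosis_reversal_frac must be in [0, 1]")
  }
  need <- d$n_global_aging + d$n_tissues * d$n_local_aging_per_tissue
  if (need > d$n_features_per_class[["miRNA"]]) {
    stop("more planted aging miRNAs than miRNA features")
  }
  d$tissues <- TISSUE_POOL[seq_len(d$n_tissues)]
  structure(d, class = "sim_design")
}

rnbinom_mu <- function(n, mu, dispersion) {
  if (dispersion <= 0) stats::rpois(n, mu) else {
    stats::rnbinom(n, mu = mu, size = 1 / dispersion)
  }
}

random_rna <- function(n, len = 22) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Simulate an aging cohort with planted aging miRNAs
#'
#' Global aging features get a monotone log-linear mean trend with a single
#' sign across all tissues; local aging features trend in exactly one
#' tissue; everything else is flat. Most piRNA features are planted at very
#' low abundance (and largely outside prepachytene clusters) so that the
#' filtering funnel has something to remove.
#'
#' @param design `sim_design`.
#' @return list with `cm` (`count_matrix`), `truth` (per-feature label,
#'   sign, local tissue), `annotation` (feature annotation table), `model`
#'   (planted per-feature/per-tissue log2 baselines and trends), `design`.
#' @export
simulate_aging_cohort <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(design$seed)
  tissues <- design$tissues
  tps <- design$timepoints
  classes <- rep(names(design$n_features_per_class),
                 design$n_features_per_class)
  n_feat <- length(classes)
  feature_id <- sprintf("%s_%03d", classes,
                        as.integer(stats::ave(seq_len(n_feat), classes,
                                              FUN = seq_along)))

  ## planted labels, only among miRNAs
  mirna_idx <- which(classes == "miRNA")
  ng <- design$n_global_aging
  nl <- design$n_local_aging_per_tissue
  label <- rep("none", n_feat)
  sign <- rep(0, n_feat)
  local_tissue <- rep(NA_character_, n_feat)
  gi <- mirna_idx[seq_len(ng)]
  label[gi] <- "global"
  sign[gi] <- rep(c(1, -1), length.out = ng)
  li <- mirna_idx[ng + seq_len(nl * length(tissues))]
  label[li] <- "local"
  sign[li] <- sample(c(1, -1), length(li), replace = TRUE)
  local_tissue[li] <- rep(tissues, each = nl)

  ## per-feature, per-tissue baselines (log2 rpmm)
  base <- matrix(stats::runif(n_feat * length(tissues), 2, 9), n_feat,
                 dimnames = list(feature_id, tissues))
  rare <- rep(FALSE, n_feat)
  if (any(classes == "piRNA")) {
    ## most piRNAs are rare artifact-like features (annotation noise)
    idx <- which(classes == "piRNA")
    rare[idx[seq_len(ceiling(0.93 * length(idx)))]] <- TRUE
    base[rare, ] <- stats::runif(sum(rare) * length(tissues), -10, -5)
  }
  ## calibrate abundant baselines so expected rpmm sums to ~1e6 per sample,
  ## keeping planted rpmm values on the real-data scale
  for (t in seq_along(tissues)) {
    base[!rare, t] <- base[!rare, t] +
      log2(1e6 / sum(2^base[!rare, t]))
  }
  trend <- matrix(0, n_feat, length(tissues),
                  dimnames = list(feature_id, tissues))
  trend[gi, ] <- sign[gi] * design$effect_slope
  for (k in seq_along(li)) {
    trend[li[k], local_tissue[li[k]]] <- sign[li[k]] * design$effect_slope
  }

  age_frac <- (tps - min(tps)) / (max(tps) - min(tps))
  sheet <- expand.grid(rep = seq_len(design$reps_per_tp), age_months = tps,
                       tissue = tissues, stringsAsFactors = FALSE)
  sheet$sample_id <- sprintf("%s_m%02d_r%d", sheet$tissue, sheet$age_months,
                             sheet$rep)
  libsize <- stats::rlnorm(nrow(sheet), design$libsize_lognorm[1],
                           design$libsize_lognorm[2])
  counts <- matrix(0, n_feat, nrow(sheet),
                   dimnames = list(feature_id, sheet$sample_id))
  for (j in seq_len(nrow(sheet))) {
    t_idx <- match(sheet$tissue[j], tissues)
    a_idx <- match(sheet$age_months[j], tps)
    mu_log2 <- base[, t_idx] + trend[, t_idx] * age_frac[a_idx]
    mu <- 2^mu_log2 * libsize[j] / 1e6
    counts[, j] <- rnbinom_mu(n_feat, mu, design$nb_dispersion)
  }
  samples <- data.frame(
    sample_id = sheet$sample_id, tissue = sheet$tissue,
    age_months = sheet$age_months,
    sex = sample(c("M", "F"), nrow(sheet), replace = TRUE),
    cohort = "aging", group = "none",
    total_aligned_reads = round(libsize),
    stringsAsFactors = FALSE
  )
  annotation <- data.frame(
    feature_id = feature_id, rna_class = classes,
    reference_length = ifelse(classes %in% c("miRNA", "piRNA"),
                              sample(20:32, n_feat, replace = TRUE),
                              sample(c(80:300, 1000:3000), n_feat,
                                     replace = TRUE)),
    mature_sequence = ifelse(classes == "miRNA", random_rna(n_feat),
                             NA_character_),
    prepachytene_cluster = ifelse(classes == "piRNA",
                                  stats::runif(n_feat) < 0.3, NA),
    is_first_paralog = TRUE, stringsAsFactors = FALSE
  )
  truth <- data.frame(feature_id = feature_id, rna_class = classes,
                      label = label, sign = sign,
                      local_tissue = local_tissue, stringsAsFactors = FALSE)
  list(cm = count_matrix(counts, samples), truth = truth,
       annotation = annotation,
       model = list(base = base, trend = trend, age_frac_at = function(age) {
         (age - min(tps)) / (max(tps) - min(tps))
       }),
       design = design)
}

#' Simulate an mRNA partner matrix with planted targets
#'
#' For each planted global aging miRNA, `n_targets_per_global_mirna` target
#' genes are coupled inversely to that miRNA's observed (per-tissue
#' centered) log2 rpmm across all tissues; an equal number of decoy genes
#' are coupled positively (these populate the positive-correlation control
#' set); the rest are independent. Conserved binding sites are planted with
#' a base probability per site type, multiplied by
#' `conserved_enrichment` for true (miRNA, target) pairs.
#'
#' @param sim output of [simulate_aging_cohort()].
#' @param n_null_genes independent genes to add.
#' @param site_base_prob per-site-type base probability of a conserved site
#'   on a random (miRNA, gene) pair.
#' @return list with `cm` (gene `count_matrix`, same samples), `sites`
#'   (binding-site table), `truth` (gene, mirna, role).
#' @export
simulate_mrna_partner <- function(sim, n_null_genes = 100,
                                  site_base_prob = 0.03) {
  design <- sim$design
  set.seed(design$seed + 104729L)
  mirnas <- sim$truth$feature_id[sim$truth$label == "global"]
  if (!length(mirnas)) stop("no planted global miRNAs in truth")
  n_t <- design$n_targets_per_global_mirna
  gene_rows <- list()
  for (m in mirnas) {
    if (n_t > 0) {
      gene_rows[[m]] <- data.frame(
        gene = sprintf("gene_%s_%s", c(rep("tgt", n_t), rep("pos", n_t)),
                       paste0(m, "_", c(seq_len(n_t), seq_len(n_t)))),
        mirna = m, role = rep(c("target", "decoy"), each = n_t),
        stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, c(gene_rows, list(
    data.frame(gene = sprintf("gene_null_%03d", seq_len(n_null_genes)),
               mirna = NA_character_, role = "null",
               stringsAsFactors = FALSE))))
  rownames(genes) <- NULL

  samples <- sim$cm$samples
  log_mirna <- log2(sim$cm$normalized[mirnas, , drop = FALSE] + 0.125)
  ## center miRNA log-expression within tissue so coupling reflects the
  ## age trend, not baseline differences between tissues
  for (t in unique(samples$tissue)) {
    j <- samples$tissue == t
    log_mirna[, j] <- log_mirna[, j, drop = FALSE] -
      rowMeans(log_mirna[, j, drop = FALSE])
  }
  n_s <- nrow(samples)
  base_g <- stats::runif(nrow(genes), 4, 9)
  mu_log2 <- matrix(rep(base_g, n_s), nrow(genes), n_s,
                    dimnames = list(genes$gene, samples$sample_id))
  beta <- design$target_beta
  for (i in seq_len(nrow(genes))) {
    if (genes$role[i] == "target") {
      mu_log2[i, ] <- mu_log2[i, ] - beta * log_mirna[genes$mirna[i], ]
    } else if (genes$role[i] == "decoy") {
      mu_log2[i, ] <- mu_log2[i, ] + beta * log_mirna[genes$mirna[i], ]
    }
  }
  libsize <- stats::rlnorm(n_s, log(1e7), 0.2)
  counts <- matrix(0, nrow(genes), n_s, dimnames = dimnames(mu_log2))
  for (j in seq_len(n_s)) {
    counts[, j] <- rnbinom_mu(nrow(genes), 2^mu_log2[, j] * libsize[j] / 1e6,
                              design$nb_dispersion)
  }
  gs <- samples
  gs$total_aligned_reads <- round(libsize)
  cm <- count_matrix(counts, gs)

  ## binding sites: enriched on true-target pairs. Same-sign global miRNAs
  ## are treated as one seed family (as for the miR-29 family, conserved
  ## seed-match sites are shared by family members), so a target gene is
  ## enriched for every miRNA of its regulator's family.
  mirna_sign <- sim$truth$sign[match(mirnas, sim$truth$feature_id)]
  names(mirna_sign) <- mirnas
  gene_family <- ifelse(genes$role == "target",
                        mirna_sign[genes$mirna], NA)
  site_rows <- list()
  k <- 1
  for (m in mirnas) {
    for (i in seq_len(nrow(genes))) {
      enriched <- !is.na(gene_family[i]) && gene_family[i] == mirna_sign[m]
      p <- min(0.9, site_base_prob *
                 if (enriched) design$conserved_enrichment else 1)
      for (st in SITE_TYPES) {
        if (stats::runif(1) < p) {
          site_rows[[k]] <- data.frame(mirna = m, gene = genes$gene[i],
                                       site_type = st, conserved = TRUE,
                                       stringsAsFactors = FALSE)
          k <- k + 1
        }
        if (stats::runif(1) < 0.05) {
          site_rows[[k]] <- data.frame(mirna = m, gene = genes$gene[i],
                                       site_type = st, conserved = FALSE,
                                       stringsAsFactors = FALSE)
          k <- k + 1
        }
      }
    }
  }
  sites <- if (length(site_rows)) do.call(rbind, site_rows) else
    data.frame(mirna = character(), gene = character(),
               site_type = character(), conserved = logical())
  list(cm = cm, sites = sites, truth = genes)
}

#' Simulate a heterochronic parabiosis cohort
#'
#' Four groups: isochronic young (IY, 3 months), heterochronic young (HY),
#' heterochronic aged (HA) and isochronic aged (IA, 21 months). IY/IA
#' means equal the aging cohort's planted means at 3 and 21 months. For
#' features flagged reversible (the planted global aging miRNAs), the HA
#' mean is pulled from the aged mean toward the young mean by
#' `parabiosis_reversal_frac` and the HY mean from young toward aged by
#' `parabiosis_accel_frac`; interpolation is linear on the rpmm scale.
#'
#' @param sim output of [simulate_aging_cohort()].
#' @param noiseless if `TRUE`, the normalized matrix carries the exact
#'   planted rpmm means (counts are their rounded library-scaled values);
#'   used for closed-form checks of effect-size ratios.
#' @return list with `cm` (`count_matrix` with parabiosis groups), `truth`
#'   (feature, reversible flag).
#' @export
simulate_parabiosis <- function(sim, noiseless = FALSE) {
  design <- sim$design
  set.seed(design$seed + 7919L)
  tissues <- design$tissues
  f_young <- sim$model$age_frac_at(3)
  f_aged <- sim$model$age_frac_at(21)
  feature_id <- rownames(sim$model$base)
  reversible <- sim$truth$label == "global"
  groups <- c("IY", "HY", "HA", "IA")
  sheet <- expand.grid(rep = seq_len(design$parab_reps), group = groups,
                       tissue = tissues, stringsAsFactors = FALSE)
  sheet$age_months <- ifelse(sheet$group %in% c("IY", "HY"), 3, 21)
  sheet$sample_id <- sprintf("pb_%s_%s_r%d", sheet$tissue, sheet$group,
                             sheet$rep)
  rpmm_mean <- matrix(0, length(feature_id), nrow(sheet),
                      dimnames = list(feature_id, sheet$sample_id))
  for (j in seq_len(nrow(sheet))) {
    t_idx <- match(sheet$tissue[j], tissues)
    young <- 2^(sim$model$base[, t_idx] + sim$model$trend[, t_idx] * f_young)
    aged <- 2^(sim$model$base[, t_idx] + sim$model$trend[, t_idx] * f_aged)
    mu <- switch(sheet$group[j],
                 IY = young,
                 IA = aged,
                 HA = ifelse(reversible,
                             aged + design$parabiosis_reversal_frac *
                               (young - aged), aged),
                 HY = ifelse(reversible,
                             young + design$parabiosis_accel_frac *
                               (aged - young), young))
    rpmm_mean[, j] <- mu
  }
  samples <- data.frame(
    sample_id = sheet$sample_id, tissue = sheet$tissue,
    age_months = sheet$age_months, sex = "M", cohort = "parabiosis",
    group = sheet$group, total_aligned_reads = 0,
    stringsAsFactors = FALSE
  )
  if (noiseless) {
    lib <- rep(1e7, nrow(sheet))
    counts <- round(sweep(rpmm_mean, 2, lib / 1e6, "*"))
    samples$total_aligned_reads <- round(lib)
    cm <- count_matrix(counts, samples, normalized = rpmm_mean)
  } else {
    lib <- stats::rlnorm(nrow(sheet), design$libsize_lognorm[1],
                         design$libsize_lognorm[2])
    counts <- matrix(0, length(feature_id), nrow(sheet),
                     dimnames = dimnames(rpmm_mean))
    for (j in seq_len(nrow(sheet))) {
      counts[, j] <- rnbinom_mu(length(feature_id),
                                rpmm_mean[, j] * lib[j] / 1e6,
                                design$nb_dispersion)
    }
    samples$total_aligned_reads <- round(lib)
    cm <- count_matrix(counts, samples)
  }
  list(cm = cm,
       truth = data.frame(feature_id = feature_id, reversible = reversible,
                          stringsAsFactors = FALSE))
}

#' Simulate read-alignment intervals
#'
#' Fragments are placed uniformly on each reference; short classes (miRNA,
#' piRNA) are read full length with high probability, long classes yield
#' partial fragments, so coverage fraction decreases with reference length
#' in expectation.
#'
#' @param annotation feature annotation with `feature_id`,
#'   `reference_length`, `rna_class`.
#' @param mean_frag_len mean fragment length for partial reads (nt).
#' @param depth expected reads per feature (Poisson).
#' @param full_length_prob named vector of per-class probabilities that a
#'   read spans the whole reference; classes not named use `default`.
#' @param default default full-length probability.
#' @param seed RNG seed.
#' @return named list mapping feature id to a 2-column interval matrix;
#'   features with zero reads are omitted.
#' @export
simulate_intervals <- function(annotation, mean_frag_len = 30, depth = 20,
                               full_length_prob = c(miRNA = 0.9, piRNA = 0.9),
                               default = 0.05, seed = 1) {
  set.seed(seed)
  out <- list()
  for (i in seq_len(nrow(annotation))) {
    n <- stats::rpois(1, depth)
    if (n == 0) next
    L <- annotation$reference_length[i]
    p_full <- full_length_prob[annotation$rna_class[i]]
    if (is.na(p_full)) p_full <- default
    full <- stats::runif(n) < p_full
    len <- ifelse(full, L, pmax(1, pmin(L - 1, stats::rpois(n, mean_frag_len))))
    start <- floor(stats::runif(n) * (L - len + 1))
    out[[annotation$feature_id[i]]] <-
      cbind(start = start, end = start + len)
  }
  out
}
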