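# miRNA-mRNA target inference by inverse expression correlation, the
# positive-correlation control, conserved binding-site enrichment, and
# target-set overlap summaries.

#' Call miRNA-mRNA target pairs by expression correlation
#'
#' Per tissue, Spearman rho between each miRNA's and each gene's rpmm
#' across matched samples. A pair is called when the criterion
#' (`rho < -target_rho_cut` with `p < target_p_cut` for `direction =
#' "inverse"`; mirrored `rho > +target_rho_cut` for `"positive"`) holds in
#' at least `min_tissues` tissues.
#'
#' @param mirna_cm miRNA `count_matrix`.
#' @param mrna_cm gene `count_matrix` sharing sample ids with `mirna_cm`.
#' @param mirnas miRNA feature ids to test.
#' @param th [nc_thresholds()].
#' @param min_tissues minimum supporting tissues (default 2).
#' @param direction `"inverse"` (targets) or `"positive"` (control).
#' @return list: `pairs` (mirna, gene, direction, n_support_tissues,
#'   best_rho), `support` (long per-tissue records mirna, gene, tissue,
#'   rho, p).
#' @export
call_targets <- function(mirna_cm, mrna_cm, mirnas = rownames(mirna_cm$counts),
                         th = nc_thresholds(), min_tissues = 2,
                         direction = c("inverse", "positive")) {
  direction <- match.arg(direction)
  shared <- intersect(colnames(mirna_cm$counts), colnames(mrna_cm$counts))
  if (!length(shared)) stop("no shared samples between matrices")
  mi <- cm_subset(mirna_cm, samples = shared)
  mr <- cm_subset(mrna_cm, samples = shared)
  mirnas <- intersect(mirnas, rownames(mi$counts))
  support <- list()
  for (t in unique(mi$samples$tissue)) {
    j <- mi$samples$tissue == t
    n <- sum(j)
    if (n < 3) next
    mirna_rank <- t(apply(mi$normalized[mirnas, j, drop = FALSE], 1, rank))
    gene_rank <- t(apply(mr$normalized[, j, drop = FALSE], 1, rank))
    rho <- suppressWarnings(stats::cor(t(mirna_rank), t(gene_rank)))
    ## constant vectors give NA via zero sd
    sd0_m <- apply(mirna_rank, 1, stats::sd) == 0
    sd0_g <- apply(gene_rank, 1, stats::sd) == 0
    rho[sd0_m, ] <- NA
    rho[, sd0_g] <- NA
    p <- spearman_t_pvalue(rho, n)
    hit <- if (direction == "inverse") {
      !is.na(rho) & rho < -th$target_rho_cut & p < th$target_p_cut
    } else {
      !is.na(rho) & rho > th$target_rho_cut & p < th$target_p_cut
    }
    idx <- which(hit, arr.ind = TRUE)
    if (nrow(idx)) {
      support[[t]] <- data.frame(
        mirna = mirnas[idx[, 1]], gene = rownames(mr$counts)[idx[, 2]],
        tissue = t, rho = rho[idx], p = p[idx], stringsAsFactors = FALSE)
    }
  }
  support <- if (length(support)) do.call(rbind, support) else
    data.frame(mirna = character(), gene = character(), tissue = character(),
               rho = numeric(), p = numeric())
  rownames(support) <- NULL
  key <- paste(support$mirna, support$gene, sep = "\r")
  n_sup <- table(key)
  keep_keys <- names(n_sup)[n_sup >= min_tissues]
  pairs <- if (length(keep_keys)) {
    first <- support[match(keep_keys, key), c("mirna", "gene")]
    best <- vapply(keep_keys, function(k) {
      r <- support$rho[key == k]
      r[which.max(abs(r))]
    }, numeric(1))
    data.frame(first, direction = direction,
               n_support_tissues = as.integer(n_sup[keep_keys]),
               best_rho = unname(best), stringsAsFactors = FALSE)
  } else {
    data.frame(mirna = character(), gene = character(),
               direction = character(), n_support_tissues = integer(),
               best_rho = numeric())
  }
  rownames(pairs) <- NULL
  list(pairs = pairs, support = support)
}

#' Positive-correlation control pairs
#'
#' Mirror of [call_targets()] with `rho > +target_rho_cut`; used as the
#' background when testing conserved binding-site enrichment.
#'
#' @inheritParams call_targets
#' @return as [call_targets()].
#' @export
control_targets <- function(mirna_cm, mrna_cm,
                            mirnas = rownames(mirna_cm$counts),
                            th = nc_thresholds(), min_tissues = 2) {
  call_targets(mirna_cm, mrna_cm, mirnas, th, min_tissues,
               direction = "positive")
}

#' Build one enrichment record from 2x2 counts
#'
#' `fold = (k_case/n_case) / (k_ctrl/n_ctrl)` (fractions as percentages in
#' the output), odds ratio from the cross-product, two-sided Fisher exact
#' P. A zero control numerator yields `fold = Inf` (Fisher still
#' computed).
#'
#' @param site_type label for the record.
#' @param k_case,n_case case pairs with >= 1 conserved site / all case pairs.
#' @param k_ctrl,n_ctrl control counts.
#' @return one-row data.frame.
#' @export
enrichment_result <- function(site_type, k_case, n_case, k_ctrl, n_ctrl) {
  frac_case <- 100 * k_case / n_case
  frac_ctrl <- 100 * k_ctrl / n_ctrl
  tab <- matrix(c(k_case, n_case - k_case, k_ctrl, n_ctrl - k_ctrl), 2,
                byrow = TRUE)
  ft <- stats::fisher.test(tab)
  data.frame(site_type = site_type, k_case = k_case, n_case = n_case,
             k_ctrl = k_ctrl, n_ctrl = n_ctrl, frac_case = frac_case,
             frac_ctrl = frac_ctrl,
             fold = enrichment_fold(frac_case, frac_ctrl),
             odds_ratio = (k_case * (n_ctrl - k_ctrl)) /
               ((n_case - k_case) * k_ctrl),
             p_fisher = ft$p.value, stringsAsFactors = FALSE)
}

#' Fold enrichment of two fractions
#' @param frac_case,frac_ctrl fractions (any common scale).
#' @return `frac_case / frac_ctrl` (`Inf` when the control fraction is 0).
#' @export
enrichment_fold <- function(frac_case, frac_ctrl) {
  ifelse(frac_ctrl == 0, Inf, frac_case / frac_ctrl)
}

#' Conserved binding-site enrichment in called target pairs
#'
#' For each site type (and `"any"`), counts the (miRNA, gene) pairs -
#' counted once per pair regardless of supporting tissues - with at least
#' one conserved site of that type, in the case (inverse-correlation) and
#' control (positive-correlation) sets, and tests the 2x2 table with a
#' two-sided Fisher exact test.
#'
#' @param case pairs data.frame from [call_targets()] (`$pairs`).
#' @param ctrl pairs data.frame from [control_targets()].
#' @param sites binding-site table (see [read_site_table()]).
#' @return data.frame of enrichment records (one per site type plus
#'   `"any"`).
#' @export
site_enrichment <- function(case, ctrl, sites) {
  conserved <- sites[sites$conserved, , drop = FALSE]
  pair_has <- function(pairs, type) {
    s <- if (type == "any") conserved else
      conserved[conserved$site_type == type, , drop = FALSE]
    pk <- paste(pairs$mirna, pairs$gene, sep = "\r")
    sk <- unique(paste(s$mirna, s$gene, sep = "\r"))
    sum(pk %in% sk)
  }
  out <- lapply(c(SITE_TYPES, "any"), function(type) {
    enrichment_result(type, pair_has(case, type), nrow(case),
                      pair_has(ctrl, type), nrow(ctrl))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Target-set overlaps for Venn reporting
#'
#' Counts genes in every exclusive region of the Venn diagram over the
#' given miRNAs' target sets.
#'
#' @param pairs data.frame with columns `mirna`, `gene`.
#' @return data.frame (members = "+"-joined miRNA subset, count).
#' @export
target_set_overlaps <- function(pairs) {
  mirnas <- sort(unique(pairs$mirna))
  sets <- lapply(mirnas, function(m) unique(pairs$gene[pairs$mirna == m]))
  names(sets) <- mirnas
  genes <- unique(pairs$gene)
  membership <- vapply(sets, function(s) genes %in% s,
                       logical(length(genes)))
  membership <- matrix(membership, nrow = length(genes))
  region <- apply(membership, 1, function(r) {
    paste(mirnas[r], collapse = "+")
  })
  tab <- table(region)
  data.frame(members = names(tab), count = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Three-way intersection counts (local / global / circulating miRNAs)
#'
#' Returns the sizes of all seven regions of the three-set Venn diagram.
#'
#' @param local_set,global_set,circulating_set character vectors.
#' @return named integer vector: `local_only`, `global_only`,
#'   `circulating_only`, `local_global`, `local_circulating`,
#'   `global_circulating`, `all_three`.
#' @export
circulating_intersection <- function(local_set, global_set,
                                     circulating_set) {
  l <- unique(local_set); g <- unique(global_set); c0 <- unique(circulating_set)
  all_f <- unique(c(l, g, c0))
  in_l <- all_f %in% l; in_g <- all_f %in% g; in_c <- all_f %in% c0
  c(local_only = sum(in_l & !in_g & !in_c),
    global_only = sum(!in_l & in_g & !in_c),
    circulating_only = sum(!in_l & !in_g & in_c),
    local_global = sum(in_l & in_g & !in_c),
    local_circulating = sum(in_l & !in_g & in_c),
    global_circulating = sum(!in_l & in_g & in_c),
    all_three = sum(in_l & in_g & in_c))
}

#' Circulating feature set
#'
#' Features detected at `rpmm >= rpmm_min` in strictly more than
#' `frac` of the samples of at least one group (grouping column chosen by
#' `by`, e.g. plasma vs EV fractions encoded as tissues). Note the strict
#' `>`, unlike the per-tissue abundance filter's inclusive rule.
#'
#' @param cm `count_matrix` of the circulating cohort.
#' @param th [nc_thresholds()].
#' @param by sample-sheet column defining the groups (default `tissue`).
#' @param frac detection fraction threshold (default 0.10, strict).
#' @return character vector of feature ids.
#' @export
circulating_features <- function(cm, th = nc_thresholds(), by = "tissue",
                                 frac = 0.10) {
  groups <- unique(cm$samples[[by]])
  hit <- rep(FALSE, nrow(cm$counts))
  for (g in groups) {
    j <- cm$samples[[by]] == g
    det <- rowSums(cm$normalized[, j, drop = FALSE] >= th$rpmm_min) / sum(j)
    hit <- hit | det > frac
  }
  rownames(cm$counts)[hit]
}
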