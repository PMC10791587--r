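# Sample QC and abundance filtering. All filters subset the already
# normalized matrix; rpmm values are computed once at load and never
# recomputed, so filter order cannot change them. Each filter is idempotent.

#' Exclude samples with too few aligned reads
#'
#' Samples with `total_aligned_reads` strictly below
#' `th$min_reads_sample` (default 2 million) are removed; a sample with
#' exactly the threshold is retained.
#'
#' @param cm `count_matrix`.
#' @param th [nc_thresholds()].
#' @return `count_matrix` without the excluded samples.
#' @export
qc_exclude_samples <- function(cm, th = nc_thresholds()) {
  keep <- cm$samples$total_aligned_reads >= th$min_reads_sample
  if (!any(keep)) stop("empty cohort: all samples below read threshold")
  cm_subset(cm, samples = keep)
}

#' Retain only piRNAs from prepachytene genomic clusters
#'
#' piRNA features whose `prepachytene_cluster` flag is `FALSE` or missing
#' are dropped (annotation artifacts dominate somatic piRNA calls);
#' features of any other RNA class are untouched.
#'
#' @param cm `count_matrix`.
#' @param annotation feature annotation with `feature_id`, `rna_class`,
#'   `prepachytene_cluster`.
#' @return filtered `count_matrix`.
#' @export
filter_pirna_prepachytene <- function(cm, annotation) {
  ann <- annotation[match(rownames(cm$counts), annotation$feature_id), ]
  is_pirna <- !is.na(ann$rna_class) & ann$rna_class == "piRNA"
  in_cluster <- !is.na(ann$prepachytene_cluster) & ann$prepachytene_cluster
  cm_subset(cm, features = !is_pirna | in_cluster)
}

#' Global abundance filter
#'
#' Keep a feature iff its rpmm reaches `th$rpmm_min` (default 1) in at
#' least one sample (inclusive).
#'
#' @param cm `count_matrix` (normalized present).
#' @param th [nc_thresholds()].
#' @return filtered `count_matrix`.
#' @export
filter_abundant_global <- function(cm, th = nc_thresholds()) {
  if (nrow(cm$counts) == 0) return(cm)
  keep <- apply(cm$normalized, 1, max) >= th$rpmm_min
  cm_subset(cm, features = keep)
}

#' Per-tissue (local) abundance filter
#'
#' Within one tissue, keep a feature iff it reaches `th$rpmm_min` rpmm in
#' at least `th$local_frac` (default 10%) of that tissue's samples. The
#' fraction rule is exact (`k/n >= local_frac`, no rounding), so with 20
#' samples 2 suffices while with 24 samples 2 does not.
#'
#' @param cm `count_matrix`.
#' @param tissue tissue to restrict to; must be present.
#' @param th [nc_thresholds()].
#' @return `count_matrix` restricted to `tissue` with abundant features.
#' @export
filter_abundant_local <- function(cm, tissue, th = nc_thresholds()) {
  cmt <- cm_tissue(cm, tissue)
  n <- ncol(cmt$counts)
  frac <- rowSums(cmt$normalized >= th$rpmm_min) / n
  cm_subset(cmt, features = frac >= th$local_frac)
}

#' RNA-class composition per tissue and timepoint
#'
#' Per sample, the share of each RNA class is `100 * class counts / total
#' counts`; per (tissue, timepoint) the mean of the sample shares is taken;
#' per tissue, `mean_variance` is the mean over classes of the sample
#' variance (denominator n-1) of the timepoint shares, and a tissue is
#' `stable` when that mean variance is strictly below `th$variance_cut`
#' (percent^2 scale). Intended to be run on locally filtered data.
#'
#' @param cm `count_matrix` (one or several tissues).
#' @param annotation feature annotation with `rna_class`.
#' @param th [nc_thresholds()].
#' @return list with `shares` (tissue, timepoint, rna_class, share) and
#'   `tissue_stats` (tissue, mean_variance, stability).
#' @export
class_composition <- function(cm, annotation, th = nc_thresholds()) {
  cls <- annotation$rna_class[match(rownames(cm$counts),
                                    annotation$feature_id)]
  if (anyNA(cls)) stop("feature(s) missing from annotation")
  totals <- colSums(cm$counts)
  zero <- totals == 0
  if (any(zero)) {
    warning(sprintf("excluding %d sample(s) with zero total counts",
                    sum(zero)))
  }
  use <- which(!zero)
  classes <- sort(unique(cls))
  ## per-sample shares (percent)
  share_mat <- vapply(use, function(j) {
    s <- tapply(cm$counts[, j], factor(cls, levels = classes), sum,
                default = 0)
    100 * as.numeric(s) / totals[j]
  }, numeric(length(classes)))
  share_mat <- matrix(share_mat, nrow = length(classes))
  meta <- cm$samples[use, , drop = FALSE]
  key <- interaction(meta$tissue, meta$age_months, drop = TRUE)
  shares <- do.call(rbind, lapply(levels(key), function(k) {
    j <- which(key == k)
    data.frame(tissue = meta$tissue[j[1]], timepoint = meta$age_months[j[1]],
               rna_class = classes,
               share = rowMeans(share_mat[, j, drop = FALSE]),
               stringsAsFactors = FALSE)
  }))
  rownames(shares) <- NULL
  tissue_stats <- do.call(rbind, lapply(unique(shares$tissue), function(t) {
    sub <- shares[shares$tissue == t, ]
    v <- tapply(sub$share, sub$rna_class, stats::var)
    mv <- mean(v, na.rm = TRUE)
    data.frame(tissue = t, mean_variance = mv,
               stability = ifelse(mv < th$variance_cut, "stable", "variable"),
               stringsAsFactors = FALSE)
  }))
  rownames(tissue_stats) <- NULL
  list(shares = shares, tissue_stats = tissue_stats)
}
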