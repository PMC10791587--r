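# Linear (Spearman) aging classification and nonlinear (fold-change)
# deregulation testing per tissue.

#' Spearman rank correlation with age
#'
#' Ties receive average ranks; rho is Pearson on ranks. The two-sided P
#' value uses the exact permutation distribution for n <= 9 without ties
#' and the t approximation otherwise (matching the small per-timepoint
#' group sizes where exactness matters).
#'
#' @param expr numeric vector (e.g. rpmm).
#' @param ages numeric vector of the same length (months).
#' @return list with `rho` and `p`; both `NA` (with a warning) when either
#'   vector is constant.
#' @export
spearman_age <- function(expr, ages) {
  if (length(expr) != length(ages)) stop("expr and ages differ in length")
  n <- length(expr)
  if (n < 3) stop("need at least 3 observations")
  if (stats::sd(expr) == 0 || stats::sd(ages) == 0) {
    warning("constant input: Spearman rho undefined")
    return(list(rho = NA_real_, p = NA_real_))
  }
  ties <- anyDuplicated(expr) > 0 || anyDuplicated(ages) > 0
  if (n <= 9 && !ties) {
    ct <- stats::cor.test(expr, ages, method = "spearman", exact = TRUE)
    return(list(rho = unname(ct$estimate), p = ct$p.value))
  }
  r <- stats::cor(rank(expr), rank(ages))
  p <- spearman_t_pvalue(r, n)
  list(rho = r, p = p)
}

## two-sided p from the t approximation, t = r * sqrt((n-2)/(1-r^2));
## argument-first pmin/pmax keep matrix dims intact
spearman_t_pvalue <- function(r, n) {
  r <- pmax(pmin(r, 1), -1)
  p <- ifelse(abs(r) == 1, 0,
              2 * stats::pt(-abs(r * sqrt((n - 2) / (1 - r^2))), n - 2))
  pmin(p, 1)
}

#' Per-tissue age correlations for every feature
#'
#' For each requested tissue, features are first passed through the local
#' abundance filter (the correlation is only meaningful for features
#' expressed in that tissue), then rho and p are computed feature-wise
#' against sample age. Constant features get `NA`.
#'
#' @param cm multi-tissue `count_matrix`.
#' @param th [nc_thresholds()].
#' @param tissues tissues to analyze (default: all in `cm`).
#' @param local_filter apply [filter_abundant_local()] first (default TRUE).
#' @return data.frame (feature_id, tissue, rho, p, n).
#' @export
age_correlation_table <- function(cm, th = nc_thresholds(),
                                  tissues = unique(cm$samples$tissue),
                                  local_filter = TRUE) {
  out <- lapply(tissues, function(t) {
    cmt <- if (local_filter) filter_abundant_local(cm, t, th) else
      cm_tissue(cm, t)
    if (nrow(cmt$counts) == 0) return(NULL)
    ages <- cmt$samples$age_months
    n <- length(ages)
    age_rank <- rank(ages)
    expr_rank <- t(apply(cmt$normalized, 1, rank))
    rho <- suppressWarnings(as.numeric(stats::cor(t(expr_rank), age_rank)))
    const <- apply(cmt$normalized, 1, function(x) stats::sd(x) == 0)
    rho[const] <- NA_real_
    p <- ifelse(is.na(rho), NA_real_, spearman_t_pvalue(rho, n))
    data.frame(feature_id = rownames(cmt$counts), tissue = t, rho = rho,
               p = p, n = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Classify features into global / local / non-aging
#'
#' A feature is *globally aging* when its rho exceeds `th$rho_cut` with the
#' same sign in strictly more than `th$n_tissues_global` tissues
#' (`global_pos` / `global_neg`); *local* when at least one tissue exceeds
#' the +-`rho_cut` interval without qualifying as global; otherwise
#' `none`. For local calls, `local_tissue` names the tissue with the
#' largest |rho| among those exceeding the cutoff.
#'
#' @param corr data.frame from [age_correlation_table()].
#' @param th [nc_thresholds()].
#' @return data.frame (feature_id, n_pos_tissues, n_neg_tissues, label,
#'   local_tissue).
#' @export
classify_aging <- function(corr, th = nc_thresholds()) {
  split_f <- split(corr, corr$feature_id)
  out <- lapply(split_f, function(d) {
    pos <- !is.na(d$rho) & d$rho > th$rho_cut
    neg <- !is.na(d$rho) & d$rho < -th$rho_cut
    label <- if (sum(pos) > th$n_tissues_global) "global_pos"
    else if (sum(neg) > th$n_tissues_global) "global_neg"
    else if (any(pos | neg)) "local"
    else "none"
    lt <- NA_character_
    if (label == "local") {
      exc <- which(pos | neg)
      lt <- d$tissue[exc[which.max(abs(d$rho[exc]))]]
    }
    data.frame(feature_id = d$feature_id[1], n_pos_tissues = sum(pos),
               n_neg_tissues = sum(neg), label = label, local_tissue = lt,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Welch t-tests with BH correction for one tissue and timepoint
#'
#' Two-sided two-sample t-tests (Welch by default) of per-feature rpmm
#' between the baseline and the given timepoint; P values are
#' BH-adjusted within this (tissue, timepoint) stratum only. When either
#' group has fewer than `th$min_n_ttest` samples, no P values are
#' computed (all `NA`). A feature constant in both groups gets p = 1 when
#' the group means are equal and p = 0 otherwise.
#'
#' @param cm `count_matrix`.
#' @param tissue tissue name.
#' @param timepoint later timepoint (months).
#' @param th [nc_thresholds()].
#' @param baseline baseline age (months), default 3.
#' @param var_equal use Student's pooled-variance t-test instead of Welch.
#' @return data.frame (feature_id, p, p_adj).
#' @export
ttest_bh <- function(cm, tissue, timepoint, th = nc_thresholds(),
                     baseline = 3, var_equal = FALSE) {
  cmt <- cm_tissue(cm, tissue)
  a <- cmt$samples$age_months == baseline
  b <- cmt$samples$age_months == timepoint
  feats <- rownames(cmt$counts)
  if (sum(a) < th$min_n_ttest || sum(b) < th$min_n_ttest) {
    return(data.frame(feature_id = feats, p = NA_real_, p_adj = NA_real_,
                      stringsAsFactors = FALSE))
  }
  p <- vapply(feats, function(f) {
    x <- cmt$normalized[f, a]
    y <- cmt$normalized[f, b]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      return(if (mean(x) == mean(y)) 1 else 0)
    }
    tryCatch(stats::t.test(x, y, var.equal = var_equal)$p.value,
             error = function(e) if (mean(x) == mean(y)) 1 else 0)
  }, numeric(1))
  data.frame(feature_id = feats, p = unname(p),
             p_adj = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE)
}

#' Fold-change deregulation table for one tissue
#'
#' Per feature and later timepoint, `fc = mean rpmm(timepoint) / mean
#' rpmm(baseline)`; features with zero baseline mean are excluded. A
#' record is *deregulated* when fc lies strictly outside
#' \[`th$fc_low`, `th$fc_high`\] (fold-change criterion alone; the
#' significance flag is reported separately). `log2fc` is `NA` where
#' fc = 0. P values come from [ttest_bh()] per timepoint (NA where group
#' sizes are insufficient); `significant` is `p_adj < th$dereg_p_cut`.
#'
#' @param cm `count_matrix`.
#' @param tissue tissue name; must contain the baseline timepoint.
#' @param th [nc_thresholds()].
#' @param baseline baseline age in months (default 3).
#' @param timepoints later timepoints to compare (default: all ages above
#'   the baseline present in the tissue).
#' @param with_p compute t-test P values (default TRUE).
#' @return data.frame (feature_id, tissue, timepoint, fc, log2fc, p,
#'   p_adj, deregulated, significant).
#' @export
foldchange_table <- function(cm, tissue, th = nc_thresholds(), baseline = 3,
                             timepoints = NULL, with_p = TRUE) {
  cmt <- cm_tissue(cm, tissue)
  ages <- cmt$samples$age_months
  if (!any(ages == baseline)) stop("baseline timepoint absent in ", tissue)
  if (is.null(timepoints)) {
    timepoints <- sort(unique(ages[ages > baseline]))
  }
  if (!length(timepoints)) {
    return(data.frame(feature_id = character(), tissue = character(),
                      timepoint = numeric(), fc = numeric(),
                      log2fc = numeric(), p = numeric(), p_adj = numeric(),
                      deregulated = logical(), significant = logical()))
  }
  base_mean <- rowMeans(cmt$normalized[, ages == baseline, drop = FALSE])
  keep <- base_mean > 0
  out <- lapply(timepoints, function(tp) {
    tp_mean <- rowMeans(cmt$normalized[, ages == tp, drop = FALSE])
    fc <- tp_mean[keep] / base_mean[keep]
    d <- data.frame(feature_id = rownames(cmt$counts)[keep], tissue = tissue,
                    timepoint = tp, fc = unname(fc),
                    log2fc = ifelse(fc == 0, NA_real_, log2(fc)),
                    p = NA_real_, p_adj = NA_real_,
                    deregulated = fc < th$fc_low | fc > th$fc_high,
                    significant = NA, stringsAsFactors = FALSE)
    if (with_p) {
      tt <- ttest_bh(cm, tissue, tp, th, baseline = baseline)
      idx <- match(d$feature_id, tt$feature_id)
      d$p <- tt$p[idx]
      d$p_adj <- tt$p_adj[idx]
      d$significant <- !is.na(d$p_adj) & d$p_adj < th$dereg_p_cut
    }
    d
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Count deregulated features per tissue and timepoint
#'
#' @param records data.frame from [foldchange_table()] (possibly several
#'   tissues bound together).
#' @param cap optional display cap: counts above it are set to the cap
#'   (e.g. 100 in heatmap displays).
#' @return tissue x timepoint integer matrix.
#' @export
deregulated_counts <- function(records, cap = NULL) {
  tab <- stats::xtabs(deregulated ~ tissue + timepoint, data = records)
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab), dimnames = dimnames(tab))
  if (!is.null(cap)) m[m > cap] <- as.integer(cap)
  m
}
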