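# Heterochronic parabiosis effects: rejuvenation (REJ, heterochronic aged
# vs isochronic aged), accelerated aging (ACC, heterochronic young vs
# isochronic young) and physiological aging (AGE, 21 vs 3 months from the
# aging cohort) fold changes, with deregulation requiring both the fold
# change and a significant P value, and classification into the six
# comparison groups.

PARABIOSIS_GROUPS <- c("IY", "HY", "HA", "IA")

#' Classify one feature's parabiosis comparison group
#'
#' Pure function of the three (FC, P) pairs. Deregulation in a contrast
#' means FC strictly outside \[`fc_low`, `fc_high`\] AND `p <
#' dereg_p_cut`. Precedence (mutually exclusive):
#'
#' 1. `REJ_up_AGE_down` / `REJ_down_AGE_up`: REJ and AGE both deregulated
#'    with opposite direction (aging change reversed by parabiosis).
#' 2. `AGE_ACC_up` / `AGE_ACC_down`: AGE and ACC both deregulated with the
#'    same direction (aging change reproduced in the young partner).
#' 3. `REJ_unique`: only REJ deregulated; `ACC_unique`: only ACC.
#' 4. `none` otherwise.
#'
#' @param fc_rej,p_rej,fc_acc,p_acc,fc_age,p_age fold changes and P values
#'   (vectors recycle elementwise).
#' @param th [nc_thresholds()].
#' @return character vector of group labels.
#' @export
parabiosis_group <- function(fc_rej, p_rej, fc_acc, p_acc, fc_age, p_age,
                             th = nc_thresholds()) {
  dereg <- function(fc, p) {
    !is.na(fc) & is.finite(fc) & (fc < th$fc_low | fc > th$fc_high) &
      !is.na(p) & p < th$dereg_p_cut
  }
  d_rej <- dereg(fc_rej, p_rej)
  d_acc <- dereg(fc_acc, p_acc)
  d_age <- dereg(fc_age, p_age)
  rej_up <- fc_rej > 1
  acc_up <- fc_acc > 1
  age_up <- fc_age > 1
  out <- rep("none", length(d_rej))
  cross_rej <- d_rej & d_age & (rej_up != age_up)
  out[cross_rej & rej_up] <- "REJ_up_AGE_down"
  out[cross_rej & !rej_up] <- "REJ_down_AGE_up"
  co_acc <- !cross_rej & d_age & d_acc & (acc_up == age_up)
  out[co_acc & age_up] <- "AGE_ACC_up"
  out[co_acc & !age_up] <- "AGE_ACC_down"
  uniq_rej <- d_rej & !d_age & !d_acc
  out[out == "none" & uniq_rej] <- "REJ_unique"
  uniq_acc <- d_acc & !d_age & !d_rej
  out[out == "none" & uniq_acc] <- "ACC_unique"
  out
}

#' Parabiosis effect records for one tissue
#'
#' Mean-based fold changes with Welch t-tests: `fc_rej` = mean(HA) /
#' mean(IA), `fc_acc` = mean(HY) / mean(IY), `fc_age` = mean(21 m) /
#' mean(3 m) from the aging cohort. Features absent from the aging cohort
#' tissue (or with zero 3-month mean) get `fc_age = NA` and are treated as
#' not age-deregulated. Features with zero denominator within the
#' parabiosis contrast get `fc = Inf` (or `NaN` for 0/0, never
#' deregulated).
#'
#' @param parab_cm parabiosis `count_matrix` (groups IY/HY/HA/IA).
#' @param aging_cm aging-cohort `count_matrix` with 3- and 21-month
#'   samples, or `NULL` to skip the AGE contrast.
#' @param tissue tissue name (must exist in `parab_cm`; all four groups
#'   required).
#' @param th [nc_thresholds()].
#' @param age_young,age_old ages defining the AGE contrast (months).
#' @return data.frame (feature_id, tissue, fc_rej, p_rej, fc_acc, p_acc,
#'   fc_age, p_age, dereg_rej, dereg_acc, dereg_age, group).
#' @export
parabiosis_effects <- function(parab_cm, aging_cm, tissue,
                               th = nc_thresholds(), age_young = 3,
                               age_old = 21) {
  cmt <- cm_tissue(parab_cm, tissue)
  miss <- setdiff(PARABIOSIS_GROUPS, unique(cmt$samples$group))
  if (length(miss)) stop("missing parabiosis group(s): ",
                         paste(miss, collapse = ", "))
  feats <- rownames(cmt$counts)
  grp <- function(g) cmt$normalized[, cmt$samples$group == g, drop = FALSE]
  contrast <- function(num, den) {
    fc <- rowMeans(num) / rowMeans(den)
    p <- vapply(seq_along(feats), function(i) {
      x <- num[i, ]
      y <- den[i, ]
      if (length(x) < th$min_n_ttest || length(y) < th$min_n_ttest) {
        return(NA_real_)
      }
      if (stats::sd(x) == 0 && stats::sd(y) == 0) {
        return(if (mean(x) == mean(y)) 1 else 0)
      }
      tryCatch(stats::t.test(x, y)$p.value,
               error = function(e) if (mean(x) == mean(y)) 1 else 0)
    }, numeric(1))
    list(fc = fc, p = p)
  }
  rej <- contrast(grp("HA"), grp("IA"))
  acc <- contrast(grp("HY"), grp("IY"))
  fc_age <- rep(NA_real_, length(feats))
  p_age <- rep(NA_real_, length(feats))
  if (!is.null(aging_cm) && tissue %in% aging_cm$samples$tissue) {
    at <- cm_tissue(aging_cm, tissue)
    common <- intersect(feats, rownames(at$counts))
    if (length(common)) {
      young <- at$normalized[common, at$samples$age_months == age_young,
                             drop = FALSE]
      old <- at$normalized[common, at$samples$age_months == age_old,
                           drop = FALSE]
      age <- contrast(old, young)
      idx <- match(common, feats)
      fc_age[idx] <- age$fc
      p_age[idx] <- age$p
    }
  }
  dereg <- function(fc, p) {
    !is.na(fc) & is.finite(fc) & (fc < th$fc_low | fc > th$fc_high) &
      !is.na(p) & p < th$dereg_p_cut
  }
  data.frame(
    feature_id = feats, tissue = tissue,
    fc_rej = unname(rej$fc), p_rej = unname(rej$p),
    fc_acc = unname(acc$fc), p_acc = unname(acc$p),
    fc_age = fc_age, p_age = p_age,
    dereg_rej = dereg(rej$fc, rej$p), dereg_acc = dereg(acc$fc, acc$p),
    dereg_age = dereg(fc_age, p_age),
    group = parabiosis_group(rej$fc, rej$p, acc$fc, acc$p, fc_age, p_age,
                             th),
    stringsAsFactors = FALSE
  )
}

#' Per-feature reversal summary (z-score effect sizes)
#'
#' Z-scores of the feature's rpmm across all parabiosis samples of the
#' tissue; group means of the z-scores; `effect_rej = |z(IA) - z(HA)|`
#' (how far the heterochronic aged moved from the isochronic aged),
#' `effect_acc = |z(HY) - z(IY)|`, and their ratio (`NA` when
#' `effect_acc` is 0).
#'
#' @param parab_cm parabiosis `count_matrix`.
#' @param feature feature id.
#' @param tissue tissue name.
#' @return one-row data.frame with the four group z-means, the two effect
#'   sizes and `rej_to_acc_ratio`; `NULL` (with a warning) for a
#'   zero-variance feature.
#' @export
reversal_summary <- function(parab_cm, feature, tissue) {
  cmt <- cm_tissue(parab_cm, tissue)
  x <- cmt$normalized[feature, ]
  if (stats::sd(x) == 0) {
    warning("zero-variance feature: ", feature)
    return(NULL)
  }
  z <- (x - mean(x)) / stats::sd(x)
  zm <- vapply(PARABIOSIS_GROUPS, function(g) {
    mean(z[cmt$samples$group == g])
  }, numeric(1))
  effect_rej <- abs(zm["IA"] - zm["HA"])
  effect_acc <- abs(zm["HY"] - zm["IY"])
  data.frame(feature_id = feature, tissue = tissue,
             z_IY = zm["IY"], z_HY = zm["HY"], z_HA = zm["HA"],
             z_IA = zm["IA"],
             effect_rej = unname(effect_rej),
             effect_acc = unname(effect_acc),
             rej_to_acc_ratio = if (effect_acc > 0)
               unname(effect_rej / effect_acc) else NA_real_,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Count parabiosis groups per tissue
#'
#' @param records data.frame from [parabiosis_effects()] (one or several
#'   tissues).
#' @param cap optional display cap (e.g. 100).
#' @return tissue x group integer matrix covering the six comparison
#'   groups.
#' @export
parabiosis_group_counts <- function(records, cap = NULL) {
  lev <- c("REJ_unique", "ACC_unique", "REJ_up_AGE_down", "REJ_down_AGE_up",
           "AGE_ACC_up", "AGE_ACC_down")
  tab <- table(factor(records$tissue), factor(records$group, levels = lev))
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab), dimnames = dimnames(tab))
  if (!is.null(cap)) m[m > cap] <- as.integer(cap)
  m
}
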