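#' Count matrix with per-sample metadata
#'
#' The central container of the workflow: a feature x sample matrix of raw
#' read counts together with a sample sheet, and an rpmm (reads per mapped
#' million) normalized matrix. Normalization is performed once at
#' construction, from the in-matrix per-sample totals, and is never redone
#' by downstream filters: dropping features therefore cannot change rpmm
#' values.
#'
#' The sample sheet must carry the columns `sample_id`, `tissue`,
#' `age_months`, `sex` (M/F), `cohort` (aging/parabiosis), `group`
#' (IY/HY/HA/IA/none) and `total_aligned_reads`. `group` must be `"none"`
#' exactly for aging-cohort samples.
#'
#' @param counts feature x sample matrix of non-negative integer counts with
#'   rownames (feature ids) and colnames (sample ids).
#' @param samples data.frame sample sheet; rows are matched to matrix
#'   columns by `sample_id` and reordered to the matrix column order.
#' @param normalized optional precomputed rpmm matrix; computed from
#'   `counts` when `NULL`.
#' @return object of class `count_matrix`: list with elements `counts`,
#'   `samples`, `normalized`.
#' @export
count_matrix <- function(counts, samples, normalized = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have feature rownames")
  if (is.null(colnames(counts))) stop("counts must have sample colnames")
  bad <- which(counts < 0 | (is.finite(counts) & counts != round(counts)),
               arr.ind = TRUE)
  if (nrow(counts) > 0 && nrow(bad) > 0) {
    stop(sprintf("negative or non-integer count at feature '%s', sample '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  }
  if (anyNA(counts)) {
    bad <- which(is.na(counts), arr.ind = TRUE)
    stop(sprintf("missing count at feature '%s', sample '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  }
  samples <- validate_sample_sheet(samples)
  missing <- setdiff(colnames(counts), samples$sample_id)
  if (length(missing)) {
    stop("sample(s) absent from sample sheet: ",
         paste(missing, collapse = ", "))
  }
  samples <- samples[match(colnames(counts), samples$sample_id), ,
                     drop = FALSE]
  rownames(samples) <- NULL
  if (is.null(normalized)) normalized <- rpmm_normalize(counts)
  stopifnot(identical(dim(normalized), dim(counts)))
  structure(list(counts = counts, samples = samples, normalized = normalized),
            class = "count_matrix")
}

validate_sample_sheet <- function(samples) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("sample_id", "tissue", "age_months", "sex", "cohort", "group",
            "total_aligned_reads")
  miss <- setdiff(need, names(samples))
  if (length(miss)) {
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id in sheet")
  if (any(samples$age_months <= 0)) stop("age_months must be > 0")
  if (any(samples$total_aligned_reads < 0)) {
    stop("total_aligned_reads must be >= 0")
  }
  if (!all(samples$sex %in% c("M", "F"))) stop("sex must be M or F")
  if (!all(samples$cohort %in% c("aging", "parabiosis"))) {
    stop("cohort must be 'aging' or 'parabiosis'")
  }
  if (!all(samples$group %in% c("IY", "HY", "HA", "IA", "none"))) {
    stop("group must be one of IY, HY, HA, IA, none")
  }
  if (any((samples$cohort == "aging") != (samples$group == "none"))) {
    stop("group must be 'none' exactly for aging-cohort samples")
  }
  samples
}

#' rpmm normalization
#'
#' `rpmm_j(f) = counts_j(f) * 1e6 / sum_f counts_j(f)`. Samples whose total
#' is zero get an all-zero column.
#'
#' @param counts feature x sample count matrix.
#' @return matrix of the same shape.
#' @export
rpmm_normalize <- function(counts) {
  totals <- colSums(counts)
  scale <- ifelse(totals > 0, 1e6 / totals, 0)
  sweep(counts, 2, scale, "*")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples (%d tissue(s), %s cohort)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$samples$tissue)),
              paste(unique(x$samples$cohort), collapse = "+")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix
#'
#' Feature and/or sample subsetting; the normalized matrix is subset in
#' lockstep (never recomputed).
#'
#' @param cm `count_matrix`.
#' @param features character or logical/integer index over features.
#' @param samples character (sample ids) or logical/integer index.
#' @return `count_matrix`.
#' @export
cm_subset <- function(cm, features = NULL, samples = NULL) {
  fi <- if (is.null(features)) seq_len(nrow(cm$counts)) else features
  si <- if (is.null(samples)) seq_len(ncol(cm$counts)) else samples
  if (is.character(si)) si <- match(si, colnames(cm$counts))
  out <- cm
  out$counts <- cm$counts[fi, si, drop = FALSE]
  out$normalized <- cm$normalized[fi, si, drop = FALSE]
  out$samples <- cm$samples[si, , drop = FALSE]
  rownames(out$samples) <- NULL
  out
}

#' Restrict a count matrix to one tissue
#' @param cm `count_matrix`.
#' @param tissue tissue name; must be present.
#' @return `count_matrix` with that tissue's samples only.
#' @export
cm_tissue <- function(cm, tissue) {
  keep <- cm$samples$tissue == tissue
  if (!any(keep)) stop("tissue not present: ", tissue)
  cm_subset(cm, samples = keep)
}
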