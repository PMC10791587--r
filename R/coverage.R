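# Covered-sequence statistics from read-alignment intervals. Long ncRNAs
# are sequenced as fragments; these statistics quantify how much of each
# reference is recovered and the longest contiguous stretch assembled from
# overlapping (or touching) reads.

#' Merge intervals (sort-merge union)
#'
#' Intervals are 0-based half-open; touching intervals `(a,b), (b,c)` merge
#' into one block of length `c - a`.
#'
#' @param intervals 2-column matrix (start, end).
#' @return merged 2-column matrix, sorted by start.
#' @export
merge_intervals <- function(intervals) {
  iv <- matrix(as.numeric(intervals), ncol = 2)
  iv <- iv[order(iv[, 1], iv[, 2]), , drop = FALSE]
  if (nrow(iv) == 0) return(iv)
  out <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1) for (i in 2:nrow(iv)) {
    last <- nrow(out)
    if (iv[i, 1] <= out[last, 2]) {
      out[last, 2] <- max(out[last, 2], iv[i, 2])
    } else {
      out <- rbind(out, iv[i, , drop = FALSE])
    }
  }
  out
}

#' Coverage statistics for one feature
#'
#' * `covered_length`: size of the union of the intervals (nt)
#' * `covered_pct`: `100 * covered_length / reference_length`
#' * `maximal_assembly`: length of the longest merged contiguous block
#'   (the longest stretch reconstructable from overlapping reads)
#' * `longest_read`, `total_reads`, `mean_read_len`: raw per-read stats
#'   (before merging)
#'
#' An empty interval list yields an all-zero record.
#'
#' @param feature_id feature name.
#' @param reference_length reference length (nt).
#' @param intervals 2-column matrix of 0-based half-open intervals, or
#'   `NULL`/0-row for an undetected feature.
#' @return one-row data.frame (a coverage record).
#' @export
coverage_record <- function(feature_id, reference_length, intervals = NULL) {
  if (is.null(intervals) || nrow(as.matrix(intervals)) == 0) {
    return(data.frame(feature_id = feature_id,
                      reference_length = reference_length,
                      covered_length = 0, covered_pct = 0,
                      maximal_assembly = 0, longest_read = 0,
                      total_reads = 0L, mean_read_len = 0,
                      stringsAsFactors = FALSE))
  }
  iv <- matrix(as.numeric(intervals), ncol = 2)
  if (any(iv[, 1] < 0) || any(iv[, 2] > reference_length)) {
    stop("interval outside [0, reference_length] for ", feature_id)
  }
  if (any(iv[, 2] <= iv[, 1])) stop("empty interval for ", feature_id)
  merged <- merge_intervals(iv)
  lens <- merged[, 2] - merged[, 1]
  raw <- iv[, 2] - iv[, 1]
  data.frame(feature_id = feature_id, reference_length = reference_length,
             covered_length = sum(lens),
             covered_pct = 100 * sum(lens) / reference_length,
             maximal_assembly = max(lens), longest_read = max(raw),
             total_reads = nrow(iv), mean_read_len = mean(raw),
             stringsAsFactors = FALSE)
}

#' Coverage table for an interval map
#'
#' @param intervals named list of interval matrices (see
#'   [read_intervals()]).
#' @param annotation feature annotation providing `reference_length`;
#'   features in the annotation but absent from the map get zero records.
#' @return data.frame of coverage records.
#' @export
coverage_table <- function(intervals, annotation) {
  recs <- lapply(seq_len(nrow(annotation)), function(i) {
    f <- annotation$feature_id[i]
    coverage_record(f, annotation$reference_length[i], intervals[[f]])
  })
  do.call(rbind, recs)
}

#' Spearman correlation of assembly fraction with reference length
#'
#' Correlates `maximal_assembly / reference_length` against
#' `reference_length` across features: a negative rho means longer RNAs
#' are proportionally less completely assembled from reads.
#'
#' @param records data.frame of coverage records (>= 3 rows).
#' @return list with `rho` and `p` (both `NA` with a warning for constant
#'   input).
#' @export
assembly_length_correlation <- function(records) {
  if (nrow(records) < 3) stop("need at least 3 coverage records")
  frac <- records$maximal_assembly / records$reference_length
  len <- records$reference_length
  if (stats::sd(frac) == 0 || stats::sd(len) == 0) {
    warning("constant input: Spearman rho undefined")
    return(list(rho = NA_real_, p = NA_real_))
  }
  spearman_age(frac, len)
}
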