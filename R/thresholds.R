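#' Analysis thresholds
#'
#' Bundle of every numeric cutoff used across the workflow, with defaults
#' matching the conventions of body-wide mouse ncRNA aging studies:
#'
#' * `rho_cut` (0.5): a miRNA counts as age-correlated in a tissue when its
#'   Spearman rho with age exceeds the interval \[-rho_cut, rho_cut\]
#'   (strict inequality).
#' * `n_tissues_global` (5): a miRNA is a *global* aging miRNA when it is
#'   age-correlated with the same sign in **more than** this many tissues.
#' * `target_rho_cut` (0.4), `target_p_cut` (0.05): inverse-correlation
#'   target calling (`rho < -0.4`, `P < 0.05`); the positive-correlation
#'   control uses the mirrored cutoff.
#' * `fc_low` (2/3), `fc_high` (3/2): fold changes strictly outside
#'   \[2/3, 3/2\] are deregulated.
#' * `dereg_p_cut` (0.05): significance cutoff where deregulation
#'   additionally requires a P value (parabiosis contrasts).
#' * `rpmm_min` (1): abundance cutoff in reads per mapped million.
#' * `local_frac` (0.10): per-tissue filter keeps features at
#'   `rpmm >= rpmm_min` in **at least** 10% of that tissue's samples.
#' * `min_reads_sample` (2e6): samples with fewer aligned reads are excluded.
#' * `variance_cut` (4.5): tissues whose mean variance of RNA-class count
#'   shares over timepoints is below this (percent^2 scale) are "stable".
#' * `tissue_specific_frac` (0.30): a trajectory cluster is tissue-specific
#'   when at least 30% of its members come from one tissue.
#' * `c_range` (2..20): candidate cluster numbers for fuzzy c-means.
#' * `min_n_ttest` (3): t-tests require at least this many samples per group.
#'
#' @param ... named overrides of any default.
#' @return A list of class `nc_thresholds`.
#' @export
#' @examples
#' th <- nc_thresholds(rpmm_min = 2)
#' th$rpmm_min
nc_thresholds <- function(...) {
  th <- list(
    rho_cut = 0.5,
    n_tissues_global = 5L,
    target_rho_cut = 0.4,
    target_p_cut = 0.05,
    fc_low = 2 / 3,
    fc_high = 3 / 2,
    dereg_p_cut = 0.05,
    rpmm_min = 1,
    local_frac = 0.10,
    min_reads_sample = 2e6,
    variance_cut = 4.5,
    tissue_specific_frac = 0.30,
    c_range = c(2L, 20L),
    min_n_ttest = 3L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(th))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == "")) {
      stop("unknown threshold name(s): ", paste(bad, collapse = ", "))
    }
    th[names(dots)] <- dots
  }
  validate_thresholds(th)
  structure(th, class = "nc_thresholds")
}

validate_thresholds <- function(th) {
  num <- c("rho_cut", "target_rho_cut", "target_p_cut", "fc_low", "fc_high",
           "dereg_p_cut", "rpmm_min", "local_frac", "variance_cut",
           "tissue_specific_frac")
  for (nm in num) {
    if (!is.numeric(th[[nm]]) || length(th[[nm]]) != 1 || th[[nm]] <= 0) {
      stop("threshold '", nm, "' must be a positive scalar")
    }
  }
  if (th$min_reads_sample < 0) stop("min_reads_sample must be >= 0")
  if (!(th$fc_low < 1 && 1 < th$fc_high)) stop("need fc_low < 1 < fc_high")
  if (length(th$c_range) != 2 || th$c_range[1] < 2 ||
      th$c_range[1] > th$c_range[2]) {
    stop("c_range must be an interval [lo, hi] with lo >= 2")
  }
  invisible(th)
}

#' Read thresholds from a YAML configuration file
#'
#' The YAML keys map one-to-one onto the fields of [nc_thresholds()]; keys
#' not present keep their defaults.
#'
#' @param path path to a YAML file.
#' @return `nc_thresholds` list.
#' @export
read_thresholds <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  do.call(nc_thresholds, cfg)
}
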