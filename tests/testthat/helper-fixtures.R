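# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except in the explicit IO round-trip tests.

make_samples <- function(n, tissue = "liver", age = rep(3, n),
                         cohort = "aging", group = "none",
                         reads = rep(5e6, n), prefix = "s") {
  data.frame(
    sample_id = paste0(prefix, seq_len(n)), tissue = tissue,
    age_months = age, sex = rep(c("M", "F"), length.out = n),
    cohort = cohort, group = group, total_aligned_reads = reads,
    stringsAsFactors = FALSE
  )
}

make_cm <- function(counts, ...) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("f", seq_len(nrow(counts)))
  }
  samples <- make_samples(ncol(counts), ...)
  colnames(counts) <- samples$sample_id
  count_matrix(counts, samples)
}

## count matrix with a per-sample tissue/age layout given as a data.frame
make_cm_layout <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("f", seq_len(nrow(counts)))
  }
  colnames(counts) <- samples$sample_id
  count_matrix(counts, samples)
}

default_sim <- local({
  cache <- new.env()
  function(seed = 42) {
    key <- paste0("s", seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <- simulate_aging_cohort(sim_design(seed = seed))
    }
    cache[[key]]
  }
})
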