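# End-to-end orchestration of the two cohort analyses. Stages log
# feature-count deltas after each filter so the filtering funnel is
# auditable on any dataset; every output table records the seed in a
# header comment and the manifest carries a config hash.

AGING_STAGES <- c("simulate", "qc", "pirna_filter", "global_filter",
                  "composition", "aging_classification", "deregulation",
                  "clustering", "targets")

STAGE_DEPS <- list(
  qc = "simulate", pirna_filter = "qc", global_filter = "pirna_filter",
  composition = "global_filter", aging_classification = "global_filter",
  deregulation = "global_filter", clustering = "aging_classification",
  targets = "aging_classification"
)

hash_config <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(lapply(config, function(x) if (is.function(x)) NULL else x), f)
  unname(tools::md5sum(f))
}

write_stage_table <- function(tab, out_dir, name, seed) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(out_dir, paste0(name, ".tsv"))
  con <- file(path, "w")
  writeLines(sprintf("# seed=%d", seed), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  path
}

#' Run the aging-cohort analysis pipeline
#'
#' Stage order: cohort simulation (or a supplied `count_matrix`), sample
#' QC, prepachytene piRNA filter, global abundance filter, RNA-class
#' composition, Spearman aging classification (with per-tissue local
#' filtering), fold-change deregulation, trajectory clustering, and -
#' when an mRNA partner matrix is simulated or supplied - target
#' inference. Deterministic given the config and seed.
#'
#' @param config list with elements: `design` ([sim_design()]; used when
#'   no `cm` is given), `cm`/`annotation` (pre-loaded data), `mrna`
#'   (optional list with `cm` and `sites`), `thresholds`
#'   ([nc_thresholds()]), `stages` (subset of the stage names; defaults to
#'   all), `out_dir` (optional; TSV outputs written there), `seed`.
#' @return manifest list: per-stage entries with row counts and parameter
#'   echo, the stage outputs under `$tables`, and `config_hash`.
#' @export
run_aging_pipeline <- function(config) {
  th <- config$thresholds %||% nc_thresholds()
  stages <- config$stages %||% AGING_STAGES
  seed <- config$seed %||% (config$design$seed %||% 1L)
  for (s in setdiff(stages, "simulate")) {
    dep <- STAGE_DEPS[[s]]
    if (!is.null(dep) && !(dep %in% stages)) {
      stop("stage '", s, "' requires stage '", dep,
           "' which is toggled off")
    }
  }
  manifest <- list(config_hash = hash_config(config), seed = seed,
                   stages = list(), tables = list())
  log_stage <- function(name, note, n_feat) {
    message(sprintf("[%s] %s (%d features)", name, note, n_feat))
    manifest$stages[[name]] <<- list(note = note, n_features = n_feat)
  }

  run <- function(expr, stage) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e))
    })
  }

  if (!is.null(config$cm)) {
    cm <- config$cm
    annotation <- config$annotation
    truth <- NULL
    sim <- NULL
  } else {
    if (!("simulate" %in% stages)) stop("no input matrix and simulation off")
    sim <- run(simulate_aging_cohort(config$design), "simulate")
    cm <- sim$cm
    annotation <- sim$annotation
    truth <- sim$truth
    log_stage("simulate", "synthetic aging cohort", nrow(cm$counts))
  }

  if ("qc" %in% stages) {
    n0 <- ncol(cm$counts)
    cm <- run(qc_exclude_samples(cm, th), "qc")
    log_stage("qc", sprintf("removed %d sample(s)", n0 - ncol(cm$counts)),
              nrow(cm$counts))
  }
  if ("pirna_filter" %in% stages) {
    n0 <- nrow(cm$counts)
    cm <- run(filter_pirna_prepachytene(cm, annotation), "pirna_filter")
    log_stage("pirna_filter", sprintf("dropped %d piRNA feature(s)",
                                      n0 - nrow(cm$counts)), nrow(cm$counts))
  }
  if ("global_filter" %in% stages) {
    n0 <- nrow(cm$counts)
    cm <- run(filter_abundant_global(cm, th), "global_filter")
    log_stage("global_filter", sprintf("dropped %d low-abundance feature(s)",
                                       n0 - nrow(cm$counts)),
              nrow(cm$counts))
  }
  tissues <- unique(cm$samples$tissue)
  if ("composition" %in% stages) {
    comp <- run(class_composition(cm, annotation, th), "composition")
    manifest$tables$composition <- comp$shares
    manifest$tables$tissue_stats <- comp$tissue_stats
    write_stage_table(comp$shares, config$out_dir, "composition", seed)
    log_stage("composition", sprintf("%d tissue(s)", length(tissues)),
              nrow(cm$counts))
  }
  corr <- NULL
  if ("aging_classification" %in% stages) {
    corr <- run(age_correlation_table(cm, th), "aging_classification")
    calls <- run(classify_aging(corr, th), "aging_classification")
    manifest$tables$age_correlations <- corr
    manifest$tables$aging_calls <- calls
    write_stage_table(calls, config$out_dir, "aging_calls", seed)
    log_stage("aging_classification",
              sprintf("%d global / %d local calls",
                      sum(grepl("^global", calls$label)),
                      sum(calls$label == "local")), nrow(cm$counts))
  }
  if ("deregulation" %in% stages) {
    recs <- do.call(rbind, lapply(tissues, function(t) {
      foldchange_table(cm, t, th)
    }))
    manifest$tables$deregulation <- recs
    manifest$tables$deregulated_counts <- deregulated_counts(recs)
    write_stage_table(recs, config$out_dir, "deregulation", seed)
    log_stage("deregulation", sprintf("%d deregulated records",
                                      sum(recs$deregulated)),
              nrow(cm$counts))
  }
  if ("clustering" %in% stages) {
    ## cluster the features expressed (post local filter) in every tissue
    common <- Reduce(intersect, lapply(tissues, function(t) {
      rownames(filter_abundant_local(cm, t, th)$counts)
    }))
    ts <- run(zscore_trajectories(cm, features = common), "clustering")
    sel <- run(select_c(ts, c_range = pmin(th$c_range,
                                           c(nrow(ts$matrix) - 1,
                                             nrow(ts$matrix) - 1))),
               "clustering")
    fit <- run(fuzzy_cmeans(ts, sel$c_opt, seed = seed), "clustering")
    spec_tab <- tissue_specificity(fit, ts$keys, th)
    manifest$tables$cluster_assignments <-
      cbind(ts$keys, cluster = fit$hard_labels,
            membership = fit$memberships[cbind(seq_len(nrow(ts$keys)),
                                               fit$hard_labels)])
    manifest$tables$dmin_curve <- sel$dmin_curve
    manifest$tables$cluster_specificity <- spec_tab
    write_stage_table(manifest$tables$cluster_assignments, config$out_dir,
                      "clusters", seed)
    log_stage("clustering", sprintf("c_opt=%d, %d tissue-specific clusters",
                                    sel$c_opt, sum(spec_tab$is_specific)),
              length(common))
  }
  if ("targets" %in% stages) {
    mrna <- config$mrna
    if (is.null(mrna) && !is.null(sim)) {
      mrna <- simulate_mrna_partner(sim)
    }
    if (is.null(mrna)) {
      stop("pipeline stage 'targets' failed: no mRNA matrix available")
    }
    glob <- if (!is.null(manifest$tables$aging_calls)) {
      with(manifest$tables$aging_calls,
           feature_id[grepl("^global", label)])
    } else rownames(cm$counts)
    case <- run(call_targets(cm, mrna$cm, glob, th), "targets")
    ctrl <- run(control_targets(cm, mrna$cm, glob, th), "targets")
    enr <- run(site_enrichment(case$pairs, ctrl$pairs, mrna$sites),
               "targets")
    manifest$tables$target_pairs <- case$pairs
    manifest$tables$control_pairs <- ctrl$pairs
    manifest$tables$site_enrichment <- enr
    write_stage_table(case$pairs, config$out_dir, "target_pairs", seed)
    write_stage_table(enr, config$out_dir, "site_enrichment", seed)
    log_stage("targets", sprintf("%d target pairs, %d control pairs",
                                 nrow(case$pairs), nrow(ctrl$pairs)),
              length(glob))
  }
  manifest$final_cm <- cm
  if (!is.null(truth)) manifest$truth <- truth
  if (!is.null(config$out_dir)) {
    jsonlite::write_json(
      list(config_hash = manifest$config_hash, seed = seed,
           stages = manifest$stages),
      file.path(config$out_dir, "manifest.json"), auto_unbox = TRUE,
      pretty = TRUE)
  }
  manifest
}

#' Run the parabiosis-cohort analysis pipeline
#'
#' Reuses the QC and abundance filters on the parabiosis matrix, then
#' computes per-tissue parabiosis effect records, group counts and
#' reversal summaries.
#'
#' @param config list: `parab_cm` (or `design` to simulate both cohorts),
#'   `aging_cm` (for the AGE contrast), `annotation`, `thresholds`,
#'   `out_dir`, `seed`.
#' @return manifest list with `$tables$effects`, `$tables$group_counts`.
#' @export
run_parabiosis_pipeline <- function(config) {
  th <- config$thresholds %||% nc_thresholds()
  seed <- config$seed %||% (config$design$seed %||% 1L)
  if (is.null(config$parab_cm)) {
    sim <- simulate_aging_cohort(config$design)
    pb <- simulate_parabiosis(sim)
    parab_cm <- pb$cm
    aging_cm <- sim$cm
    annotation <- sim$annotation
  } else {
    parab_cm <- config$parab_cm
    aging_cm <- config$aging_cm
    annotation <- config$annotation
  }
  manifest <- list(config_hash = hash_config(config), seed = seed,
                   tables = list())
  parab_cm <- qc_exclude_samples(parab_cm, th)
  if (!is.null(annotation)) {
    parab_cm <- filter_pirna_prepachytene(parab_cm, annotation)
  }
  parab_cm <- filter_abundant_global(parab_cm, th)
  message(sprintf("[filters] %d features retained", nrow(parab_cm$counts)))
  effects <- do.call(rbind, lapply(unique(parab_cm$samples$tissue),
                                   function(t) {
    parabiosis_effects(parab_cm, aging_cm, t, th)
  }))
  manifest$tables$effects <- effects
  manifest$tables$group_counts <- parabiosis_group_counts(effects)
  write_stage_table(effects, config$out_dir, "parabiosis_effects", seed)
  manifest$final_cm <- parab_cm
  manifest
}

`%||%` <- function(a, b) if (is.null(a)) b else a
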