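## independent truth table written from the comparison-group definitions
group_oracle <- function(fr, pr, fa, pa, fg, pg, th = nc_thresholds()) {
  dr <- (fr < th$fc_low || fr > th$fc_high) && pr < 0.05
  da <- (fa < th$fc_low || fa > th$fc_high) && pa < 0.05
  dg <- (fg < th$fc_low || fg > th$fc_high) && pg < 0.05
  if (dr && dg && ((fr > 1) != (fg > 1))) {
    if (fr > 1) "REJ_up_AGE_down" else "REJ_down_AGE_up"
  } else if (dg && da && ((fa > 1) == (fg > 1))) {
    if (fg > 1) "AGE_ACC_up" else "AGE_ACC_down"
  } else if (dr && !dg && !da) {
    "REJ_unique"
  } else if (da && !dg && !dr) {
    "ACC_unique"
  } else "none"
}

test_that("group assignment matches the exhaustive truth table", {
  fcs <- c(0.5, 1, 2)
  ps <- c(0.01, 0.5)
  grid <- expand.grid(fr = fcs, pr = ps, fa = fcs, pa = ps,
                      fg = fcs, pg = ps)
  got <- parabiosis_group(grid$fr, grid$pr, grid$fa, grid$pa,
                          grid$fg, grid$pg)
  want <- vapply(seq_len(nrow(grid)), function(i) {
    group_oracle(grid$fr[i], grid$pr[i], grid$fa[i], grid$pa[i],
                 grid$fg[i], grid$pg[i])
  }, character(1))
  expect_equal(got, want)
  ## definitional spot checks
  expect_equal(parabiosis_group(2, 0.01, 1, 0.9, 0.5, 0.01),
               "REJ_up_AGE_down")
  expect_equal(parabiosis_group(2, 0.01, 1, 0.9, 1, 0.9), "REJ_unique")
  expect_equal(parabiosis_group(1, 0.9, 1, 0.9, 1, 0.9), "none")
  ## NA and non-finite fold changes never deregulate
  expect_equal(parabiosis_group(NA, NA, 1, 0.9, 2, 0.01), "none")
  expect_equal(parabiosis_group(NaN, 0.01, 1, 0.9, 2, 0.01), "none")
})

test_that("parabiosis effects demand all four groups and report contrasts", {
  sim <- default_sim(42)
  pb <- simulate_parabiosis(sim, noiseless = TRUE)
  cm_no_hy <- cm_subset(pb$cm, samples = pb$cm$samples$group != "HY")
  expect_error(parabiosis_effects(cm_no_hy, sim$cm, "liver"), "HY")
  eff <- parabiosis_effects(pb$cm, sim$cm, "liver")
  expect_true(all(c("fc_rej", "fc_acc", "fc_age", "group") %in% names(eff)))
})

test_that("noiseless planted reversal is classified exactly", {
  sim <- default_sim(42)
  pb <- simulate_parabiosis(sim, noiseless = TRUE)
  eff <- parabiosis_effects(pb$cm, NULL, "liver")
  ## AGE contrast from noiseless group means: reuse IY/IA as 3 m / 21 m
  ## by building an aging stand-in from the parabiosis isochronic groups
  iso <- cm_subset(pb$cm, samples = pb$cm$samples$group %in% c("IY", "IA"))
  iso$samples$cohort <- "aging"
  iso$samples$group <- "none"
  eff <- parabiosis_effects(pb$cm, iso, "liver")
  rev_f <- pb$truth$feature_id[pb$truth$reversible]
  e <- eff[eff$feature_id %in% rev_f, ]
  expect_true(all(e$group %in% c("REJ_up_AGE_down", "REJ_down_AGE_up")))
  other <- eff[!(eff$feature_id %in% rev_f), ]
  expect_false(any(other$group %in% c("REJ_up_AGE_down", "REJ_down_AGE_up")))
})

test_that("noisy default design keeps specificity and beats the null rate", {
  sim <- default_sim(42)
  pb <- simulate_parabiosis(sim)
  eff <- parabiosis_effects(pb$cm, sim$cm, "liver")
  rev_f <- pb$truth$feature_id[pb$truth$reversible]
  null_f <- sim$truth$feature_id[sim$truth$label == "none"]
  rej_groups <- c("REJ_up_AGE_down", "REJ_down_AGE_up")
  sens <- mean(eff$group[eff$feature_id %in% rev_f] %in% rej_groups)
  fp <- mean(eff$group[eff$feature_id %in% null_f] %in% rej_groups)
  expect_gte(1 - fp, 0.95)
  expect_gt(sens, 10 * max(fp, 0.01))
})

test_that("reversal summary gives exact effect sizes on the noiseless design", {
  d <- sim_design(seed = 42)            # reversal 0.8, acceleration 0.2
  sim <- simulate_aging_cohort(d)
  pb <- simulate_parabiosis(sim, noiseless = TRUE)
  f <- pb$truth$feature_id[pb$truth$reversible][1]
  rs <- reversal_summary(pb$cm, f, "liver")
  expect_equal(rs$rej_to_acc_ratio, 4, tolerance = 1e-9)
  ## HA = IA means zero rejuvenation effect
  d0 <- sim_design(seed = 42, parabiosis_reversal_frac = 0,
                   parabiosis_accel_frac = 0.2)
  pb0 <- simulate_parabiosis(simulate_aging_cohort(d0), noiseless = TRUE)
  rs0 <- reversal_summary(pb0$cm, f, "liver")
  expect_equal(rs0$effect_rej, 0, tolerance = 1e-9)
  ## both effects zero -> undefined ratio sentinel
  dz <- sim_design(seed = 42, parabiosis_reversal_frac = 0,
                   parabiosis_accel_frac = 0)
  pbz <- simulate_parabiosis(simulate_aging_cohort(dz), noiseless = TRUE)
  rsz <- reversal_summary(pbz$cm, f, "liver")
  expect_true(is.na(rsz$rej_to_acc_ratio))
  ## zero-variance feature is excluded with a warning
  flat <- pbz$truth$feature_id[!pbz$truth$reversible][1]
  cmz <- pbz$cm
  cmz$normalized[flat, ] <- 5
  expect_warning(out <- reversal_summary(cmz, flat, "liver"),
                 "zero-variance")
  expect_null(out)
})

test_that("group counts tabulate per tissue with the display cap", {
  recs <- data.frame(feature_id = paste0("f", 1:130),
                     tissue = "liver",
                     group = c(rep("REJ_unique", 120), rep("AGE_ACC_up", 10)))
  m <- parabiosis_group_counts(recs)
  expect_equal(m["liver", "REJ_unique"], 120L)
  mc <- parabiosis_group_counts(recs, cap = 100)
  expect_equal(mc["liver", "REJ_unique"], 100L)
  expect_equal(mc["liver", "AGE_ACC_up"], 10L)
  empty <- recs[0, ]
  expect_true(all(parabiosis_group_counts(empty) == 0))
})
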