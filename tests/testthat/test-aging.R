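## independent oracle: mid-ranks then Pearson, p from the t formula
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  r <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  n <- length(x)
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(rho = r, p = 2 * stats::pt(-abs(t), n - 2))
}

test_that("spearman correlation matches hand examples", {
  ages <- c(1, 3, 6, 9, 12, 15)
  expect_equal(spearman_age(2^ages, ages)$rho, 1)
  expect_equal(spearman_age(rev(ages), ages)$rho, -1)
  ## ranks (2,1,4,3,6,5) against 1..6: rho = 1 - 6*6/(6*35)
  r <- spearman_age(c(2, 1, 4, 3, 6, 5), 1:6)
  expect_equal(r$rho, 1 - 36 / 210, tolerance = 1e-12)
  expect_warning(rc <- spearman_age(rep(2, 5), 1:5), "constant")
  expect_true(is.na(rc$rho))
  expect_error(spearman_age(1:3, 1:4), "length")
})

test_that("spearman agrees with the rank-Pearson oracle on fuzzed input", {
  set.seed(21)
  for (i in 1:50) {
    n <- sample(10:60, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    got <- spearman_age(x, y)
    ora <- spearman_oracle(x, y)
    expect_equal(got$rho, ora$rho, tolerance = 1e-12)
    expect_equal(got$p, ora$p, tolerance = 1e-12)
    ## with ties: mid-rank oracle
    xt <- round(x)                      # heavy ties
    got_t <- spearman_age(xt, y)
    ora_t <- spearman_oracle(xt, y)
    expect_equal(got_t$rho, ora_t$rho, tolerance = 1e-12)
  }
})

test_that("vectorized per-tissue correlations equal the scalar routine", {
  sim <- default_sim(42)
  cm <- filter_abundant_global(qc_exclude_samples(sim$cm))
  corr <- age_correlation_table(cm, tissues = "liver", local_filter = FALSE)
  cmt <- cm_tissue(cm, "liver")
  for (f in sample(corr$feature_id, 10)) {
    ref <- suppressWarnings(spearman_age(cmt$normalized[f, ],
                                         cmt$samples$age_months))
    row <- corr[corr$feature_id == f, ]
    expect_equal(row$rho, ref$rho, tolerance = 1e-12)
  }
})

test_that("aging classification applies the more-than-five same-sign rule", {
  th <- nc_thresholds()
  mk <- function(feature, rhos) {
    data.frame(feature_id = feature, tissue = paste0("t", seq_along(rhos)),
               rho = rhos, p = 0.001, n = 40)
  }
  ## rho > 0.5 in 6 tissues -> global_pos
  calls <- classify_aging(mk("a", rep(0.7, 6)), th)
  expect_equal(calls$label, "global_pos")
  ## exactly 5 tissues is not global ("more than five")
  calls5 <- classify_aging(mk("a", c(rep(0.7, 5), 0.2)), th)
  expect_equal(calls5$label, "local")
  ## mixed signs do not sum: 3 pos + 3 neg -> local
  callsm <- classify_aging(mk("a", c(0.8, 0.8, 0.8, -0.8, -0.8, -0.8)), th)
  expect_equal(callsm$label, "local")
  ## one tissue at 0.6, others inside the interval -> local with tissue
  callsl <- classify_aging(mk("a", c(0.6, 0.4, -0.3, 0.1, 0, 0.2)), th)
  expect_equal(callsl$label, "local")
  expect_equal(callsl$local_tissue, "t1")
  ## |rho| = 0.5 exactly does not exceed the interval
  calls0 <- classify_aging(mk("a", rep(0.5, 6)), th)
  expect_equal(calls0$label, "none")
  calln <- classify_aging(mk("a", rep(-0.7, 6)), th)
  expect_equal(calln$label, "global_neg")
})

test_that("fold changes use strict thresholds and drop zero baselines", {
  samples <- make_samples(8, age = rep(c(3, 12), each = 4))
  counts <- rbind(boundary = c(rep(20, 4), rep(30, 4)),
                  dereg = c(rep(20, 4), rep(40, 4)),
                  zerobase = c(rep(0, 4), rep(10, 4)),
                  filler = c(rep(1e6, 4), rep(1e6 - 30, 4)))
  cm <- make_cm_layout(counts * 50, samples)
  fc <- foldchange_table(cm, "liver", with_p = FALSE)
  expect_false("zerobase" %in% fc$feature_id)
  b <- fc[fc$feature_id == "boundary", ]
  expect_equal(b$fc, 1.5, tolerance = 1e-4)
  expect_false(b$deregulated)          # exactly 3/2 is not deregulated
  d <- fc[fc$feature_id == "dereg", ]
  expect_equal(d$fc, 2, tolerance = 1e-4)
  expect_true(d$deregulated)
  expect_error(foldchange_table(cm_subset(cm, samples = 5:8), "liver"),
               "baseline")
})

test_that("t-tests respect the minimum group size and BH corrects per stratum", {
  samples <- make_samples(5, age = c(3, 3, 12, 12, 12))
  counts <- matrix(rpois(20, 100), 4)
  cm <- make_cm_layout(counts, samples)
  tt <- ttest_bh(cm, "liver", 12)      # baseline group has n = 2
  expect_true(all(is.na(tt$p)))
  ## identical groups -> p near 1
  samples6 <- make_samples(6, age = rep(c(3, 12), each = 3))
  counts6 <- rbind(same = rep(100, 6), other = rep(500, 6))
  cm6 <- make_cm_layout(counts6, samples6)
  tt6 <- ttest_bh(cm6, "liver", 12)
  expect_equal(tt6$p[tt6$feature_id == "same"], 1)
  ## BH equals the step-up hand formula
  sim <- default_sim(42)
  tt_sim <- ttest_bh(qc_exclude_samples(sim$cm), "liver", 12)
  p <- tt_sim$p
  m <- length(p)
  o <- order(p)
  stepped <- rev(cummin(rev(p[o] * m / seq_len(m))))
  hand <- pmin(1, stepped)[order(o)]
  expect_equal(tt_sim$p_adj, hand, tolerance = 1e-12)
  expect_true(all(tt_sim$p_adj >= tt_sim$p - 1e-12))
  expect_true(all(tt_sim$p_adj <= 1))
  ## the worked example: (0.01, 0.02, 0.03, 0.04) -> all 0.04
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
})

test_that("deregulated counts tabulate per tissue and timepoint with a cap", {
  recs <- data.frame(
    feature_id = "f", tissue = rep(c("liver", "brain"), c(150, 3)),
    timepoint = 12, fc = 2, log2fc = 1, p = NA, p_adj = NA,
    deregulated = TRUE, significant = NA)
  m <- deregulated_counts(recs)
  expect_equal(m["liver", "12"], 150L)
  mc <- deregulated_counts(recs, cap = 100)
  expect_equal(mc["liver", "12"], 100L)
  expect_equal(mc["brain", "12"], 3L)
  recs0 <- recs; recs0$deregulated <- FALSE
  expect_true(all(deregulated_counts(recs0) == 0))
})
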