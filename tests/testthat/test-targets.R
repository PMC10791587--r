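## build matched miRNA/gene matrices with planted per-tissue correlations
make_pair_cms <- function(gene_fun, n_tissues = 3, n = 30, seed = 1) {
  set.seed(seed)
  samples <- do.call(rbind, lapply(seq_len(n_tissues), function(t) {
    make_samples(n, tissue = paste0("t", t), age = rep(seq_len(n / 3), 3),
                 prefix = paste0("t", t, "_s"))
  }))
  ## constant filler rows keep rpmm normalization from flattening the
  ## single planted feature
  m_expr <- rpois(nrow(samples), 500) + 1
  mirna <- rbind("miR-x" = m_expr, fill_m = rep(1e6, nrow(samples)))
  colnames(mirna) <- samples$sample_id
  genes <- vapply(seq_len(nrow(samples)), function(j) gene_fun(m_expr[j]),
                  numeric(2))
  genes <- rbind(genes, rep(1e6, nrow(samples)))
  rownames(genes) <- c("g_inv", "g_pos", "fill_g")
  colnames(genes) <- samples$sample_id
  list(mirna = count_matrix(mirna, samples),
       genes = count_matrix(round(genes), samples))
}

test_that("planted inverse and positive pairs are called with tissue support", {
  cms <- make_pair_cms(function(m) c(2000 - m + rnorm(1, 0, 5),
                                     m + rnorm(1, 0, 5)))
  case <- call_targets(cms$mirna, cms$genes, "miR-x", min_tissues = 2)
  expect_equal(case$pairs$gene, "g_inv")
  expect_equal(case$pairs$n_support_tissues, 3L)
  expect_lt(case$pairs$best_rho, -0.4)
  ctrl <- control_targets(cms$mirna, cms$genes, "miR-x", min_tissues = 2)
  expect_equal(ctrl$pairs$gene, "g_pos")
  expect_false("g_inv" %in% ctrl$pairs$gene)
})

test_that("support in a single tissue is not enough at min_tissues = 2", {
  ## inverse coupling only in tissue 1; independent elsewhere
  set.seed(2)
  counter <- new.env(); counter$j <- 0
  cms <- make_pair_cms(function(m) {
    counter$j <- counter$j + 1
    if (counter$j <= 30) c(2000 - m, rpois(1, 1000)) else
      c(rpois(1, 1000), rpois(1, 1000))
  })
  case <- call_targets(cms$mirna, cms$genes, "miR-x", min_tissues = 2)
  expect_false("g_inv" %in% case$pairs$gene)
  case1 <- call_targets(cms$mirna, cms$genes, "miR-x", min_tissues = 1)
  expect_true("g_inv" %in% case1$pairs$gene)
  ## no shared samples is an error
  mi2 <- cms$mirna; colnames(mi2$counts) <- paste0("x", seq_len(ncol(mi2$counts)))
  mi2$samples$sample_id <- colnames(mi2$counts)
  mi2$normalized <- mi2$normalized; colnames(mi2$normalized) <- colnames(mi2$counts)
  expect_error(call_targets(mi2, cms$genes, "miR-x"), "no shared samples")
})

test_that("null pairs are discovered at no more than the nominal rate", {
  set.seed(33)
  n_pairs <- 1000
  n <- 30
  samples <- make_samples(n, age = rep(1:10, 3))
  hits <- 0
  mirna <- matrix(rpois(n_pairs * n, 200), n_pairs,
                  dimnames = list(paste0("m", seq_len(n_pairs)),
                                  samples$sample_id))
  genes <- matrix(rpois(n_pairs * n, 200), n_pairs,
                  dimnames = list(paste0("g", seq_len(n_pairs)),
                                  samples$sample_id))
  mi <- count_matrix(mirna, samples)
  ge <- count_matrix(genes, samples)
  case <- call_targets(mi, ge, rownames(mirna), min_tissues = 1)
  ## per-(pair, tissue) discovery prob under the null is bounded by
  ## P(rho < -0.4), itself below the nominal p cutoff; binomial upper check
  rate <- nrow(case$support) / n_pairs^2
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / n_pairs^2))
})

test_that("enrichment arithmetic matches hand formulas and sentinels", {
  r <- enrichment_result("any", 9, 122, 120, 54992)
  expect_equal(r$frac_case, 100 * 9 / 122)
  expect_equal(r$fold, (9 / 122) / (120 / 54992), tolerance = 1e-12)
  ## hand odds ratio from the reference 2x2 layout
  r2 <- enrichment_result("any", 9, 9 + 113, 120, 120 + 54872)
  expect_equal(r2$odds_ratio, (9 * 54872) / (113 * 120), tolerance = 1e-12)
  ## zero control numerator -> infinite fold, Fisher still computed
  r3 <- enrichment_result("8mer", 5, 50, 0, 50)
  expect_equal(r3$fold, Inf)
  expect_true(is.finite(r3$p_fisher) && r3$p_fisher < 1)
  ## identical fractions -> fold 1, p 1
  r4 <- enrichment_result("8mer", 10, 100, 10, 100)
  expect_equal(r4$fold, 1)
  expect_equal(r4$p_fisher, 1)
})

test_that("Fisher exact p matches the hypergeometric tail oracle", {
  hyper_oracle <- function(k_case, n_case, k_ctrl, n_ctrl) {
    K <- k_case + k_ctrl
    support <- max(0, K - n_ctrl):min(n_case, K)
    probs <- stats::dhyper(support, n_case, n_ctrl, K)
    sum(probs[probs <= probs[support == k_case] * (1 + 1e-7)])
  }
  set.seed(8)
  for (i in 1:80) {
    n_case <- sample(1:100, 1)
    n_ctrl <- sample(1:100, 1)
    k_case <- sample(0:n_case, 1)
    k_ctrl <- sample(0:n_ctrl, 1)
    r <- enrichment_result("any", k_case, n_case, k_ctrl, n_ctrl)
    expect_equal(r$p_fisher, hyper_oracle(k_case, n_case, k_ctrl, n_ctrl),
                 tolerance = 1e-9)
  }
})

test_that("site enrichment counts pairs once and splits by site type", {
  case <- data.frame(mirna = c("m1", "m1", "m2"), gene = c("gA", "gB", "gA"))
  ctrl <- data.frame(mirna = c("m1", "m2"), gene = c("gC", "gD"))
  sites <- data.frame(
    mirna = c("m1", "m1", "m1", "m2"),
    gene = c("gA", "gA", "gB", "gD"),
    site_type = c("8mer", "8mer", "7mer-m8", "8mer"),
    conserved = c(TRUE, TRUE, TRUE, TRUE))
  enr <- site_enrichment(case, ctrl, sites)
  e8 <- enr[enr$site_type == "8mer", ]
  expect_equal(e8$k_case, 1L)          # duplicate site rows count once/pair
  expect_equal(e8$n_case, 3L)
  expect_equal(e8$k_ctrl, 1L)          # (m2, gD)
  eany <- enr[enr$site_type == "any", ]
  expect_equal(eany$k_case, 2L)        # (m1,gA), (m1,gB)
  ## non-conserved sites never count
  sites$conserved <- FALSE
  enr0 <- site_enrichment(case, ctrl, sites)
  expect_true(all(enr0$k_case == 0))
})

test_that("target set overlaps match a powerset oracle", {
  pairs <- data.frame(
    mirna = c("m1", "m1", "m1", "m2", "m2", "m3"),
    gene = c("a", "b", "c", "b", "c", "z"))
  ov <- target_set_overlaps(pairs)
  expect_equal(ov$count[ov$members == "m1"], 1L)        # a
  expect_equal(ov$count[ov$members == "m1+m2"], 2L)     # b, c
  expect_equal(ov$count[ov$members == "m3"], 1L)        # z
  ## identical sets -> all mass in the full intersection
  p2 <- data.frame(mirna = rep(c("m1", "m2"), each = 2),
                   gene = rep(c("a", "b"), 2))
  ov2 <- target_set_overlaps(p2)
  expect_equal(ov2$members, "m1+m2")
  expect_equal(ov2$count, 2L)
  ## brute-force oracle over random set systems
  set.seed(5)
  for (i in 1:10) {
    ms <- paste0("m", 1:3)
    pr <- unique(data.frame(
      mirna = sample(ms, 30, replace = TRUE),
      gene = sample(letters[1:8], 30, replace = TRUE)))
    ov3 <- target_set_overlaps(pr)
    expect_equal(sum(ov3$count), length(unique(pr$gene)))
    for (g in unique(pr$gene)) {
      members <- sort(unique(pr$mirna[pr$gene == g]))
      expect_true(paste(members, collapse = "+") %in% ov3$members)
    }
  }
})

test_that("three-way circulating intersection enumerates all regions", {
  r <- circulating_intersection(c("a", "b"), c("a", "b"), c("a", "b"))
  expect_equal(unname(r["all_three"]), 2L)
  expect_equal(sum(r), 2L)
  r2 <- circulating_intersection("a", "b", "c")
  expect_equal(unname(r2[c("local_only", "global_only", "circulating_only")]),
               c(1L, 1L, 1L))
  expect_equal(sum(r2[4:7]), 0L)
  r3 <- circulating_intersection(c("a", "b", "c"), c("b"), c("c", "d"))
  expect_equal(unname(r3["local_global"]), 1L)
  expect_equal(unname(r3["local_circulating"]), 1L)
  expect_equal(unname(r3["local_only"]), 1L)
  expect_equal(unname(r3["circulating_only"]), 1L)
})

test_that("circulating detection uses a strict >10% rule", {
  ## 20 samples in one group: 2 hits is exactly 10% -> NOT circulating
  hi <- function(k, n = 20) c(rep(2000, k), rep(0, n - k))
  counts <- rbind(at10 = hi(2), above = hi(3), filler = rep(1e6, 20))
  cm <- make_cm_layout(counts, make_samples(20, tissue = "plasma"))
  feats <- circulating_features(cm)
  expect_false("at10" %in% feats)
  expect_true("above" %in% feats)
})
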