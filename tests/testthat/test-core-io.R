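test_that("thresholds carry the documented defaults and validate overrides", {
  th <- nc_thresholds()
  expect_equal(th$rho_cut, 0.5)
  expect_equal(th$fc_low, 2 / 3)
  expect_equal(th$fc_high, 3 / 2)
  expect_equal(th$min_reads_sample, 2e6)
  expect_error(nc_thresholds(bogus = 1), "unknown threshold")
  expect_error(nc_thresholds(fc_low = 1.2), "fc_low < 1")
  th2 <- nc_thresholds(rpmm_min = 2)
  expect_equal(th2$rpmm_min, 2)
})

test_that("rpmm columns sum to 1e6 for nonzero samples", {
  set.seed(1)
  for (i in 1:5) {
    m <- matrix(rpois(60, 50), 10)
    cm <- make_cm(m)
    expect_equal(colSums(cm$normalized), rep(1e6, ncol(m)),
                 ignore_attr = TRUE, tolerance = 1e-9)
  }
  ## zero-total sample stays all-zero
  m <- matrix(c(1, 2, 0, 0), 2)
  cm <- make_cm(m)
  expect_equal(unname(cm$normalized[, 2]), c(0, 0))
})

test_that("count matrix construction rejects malformed input", {
  m <- matrix(c(1, -1, 2, 3), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(count_matrix(m, make_samples(2)), "negative or non-integer")
  m2 <- matrix(c(1, 1.5, 2, 3), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  err <- tryCatch(count_matrix(m2, make_samples(2)), error = conditionMessage)
  expect_match(err, "'b'")
  expect_match(err, "'s1'")
  ## missing sample in sheet named in the error
  m3 <- matrix(1:4, 2, dimnames = list(c("a", "b"), c("s1", "sX")))
  expect_error(count_matrix(m3, make_samples(2)), "sX")
  ## group/cohort consistency
  s <- make_samples(2)
  s$group[1] <- "IY"
  m4 <- matrix(1:4, 2, dimnames = list(c("a", "b"), s$sample_id))
  expect_error(count_matrix(m4, s), "group")
})

test_that("count matrix TSV round-trip is the identity", {
  td <- withr::local_tempdir()
  set.seed(7)
  m <- matrix(rpois(40, 20), 8)
  cm <- make_cm(m)
  p <- file.path(td, "counts.tsv")
  sp <- file.path(td, "sheet.tsv")
  write_count_matrix(cm, p, sp)
  cm2 <- read_count_matrix(p, sp)
  expect_equal(cm2$counts, cm$counts)
  expect_equal(cm2$samples, cm$samples)
  expect_equal(cm2$normalized, cm$normalized)
  ## 2x2 identity example
  m22 <- matrix(c(1, 3, 2, 4), 2, dimnames = list(c("fA", "fB"), NULL))
  cmx <- make_cm(m22)
  write_count_matrix(cmx, p, sp)
  expect_equal(unname(read_count_matrix(p, sp)$counts),
               matrix(c(1, 3, 2, 4), 2))
})

test_that("MatrixMarket counts are read with a feature sidecar", {
  td <- withr::local_tempdir()
  m <- Matrix::Matrix(matrix(c(0, 5, 3, 0, 1, 2), 3), sparse = TRUE)
  p <- file.path(td, "c.mtx")
  Matrix::writeMM(m, p)
  writeLines(c("fa", "fb", "fc"), paste0(p, ".features"))
  sheet <- make_samples(2)
  sp <- file.path(td, "sheet.tsv")
  utils::write.table(sheet, sp, sep = "\t", quote = FALSE, row.names = FALSE)
  cm <- read_count_matrix(p, sp)
  expect_equal(unname(cm$counts[, 1]), c(0, 5, 3))
  expect_equal(rownames(cm$counts), c("fa", "fb", "fc"))
})

test_that("non-first paralogs are dropped at load", {
  td <- withr::local_tempdir()
  cm <- make_cm(matrix(1:6, 3))
  p <- file.path(td, "c.tsv"); sp <- file.path(td, "s.tsv")
  write_count_matrix(cm, p, sp)
  ann <- data.frame(feature_id = c("f1", "f2", "f3"),
                    is_first_paralog = c(TRUE, FALSE, TRUE))
  expect_message(cm2 <- read_count_matrix(p, sp, annotation = ann),
                 "paralog")
  expect_equal(rownames(cm2$counts), c("f1", "f3"))
})

test_that("interval files parse, group by feature and reject empty spans", {
  td <- withr::local_tempdir()
  p <- file.path(td, "iv.bed")
  writeLines(c("f1\t0\t10", "f2\t5\t9", "f1\t20\t30"), p)
  iv <- read_intervals(p)
  expect_equal(nrow(iv$f1), 2)
  expect_equal(unname(iv$f2[1, ]), c(5, 9))
  writeLines(c("f1\t0\t10", "f1\t5\t5"), p)
  expect_error(read_intervals(p), "line 2")
  ## round trip
  writeLines(c("f1\t0\t10", "f2\t5\t9"), p)
  iv <- read_intervals(p)
  p2 <- file.path(td, "iv2.bed")
  write_intervals(iv, p2)
  expect_equal(read_intervals(p2), iv)
})

test_that("site tables normalize types, accept the 7mer-8m alias, keep duplicates", {
  td <- withr::local_tempdir()
  p <- file.path(td, "sites.tsv")
  tab <- data.frame(mirna = c("miR-29c-3p", "miR-29c-3p", "miR-1"),
                    gene = c("Col1a1", "Col1a1", "Eln"),
                    site_type = c("8MER", "8mer", "7mer-8m"),
                    conserved = c(TRUE, TRUE, FALSE))
  utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
  st <- read_site_table(p)
  expect_equal(nrow(st), 3)          # duplicates retained
  expect_equal(st$site_type, c("8mer", "8mer", "7mer-m8"))
  tab$site_type[1] <- "9mer"
  utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_site_table(p), "unknown site type")
})

test_that("cm_subset keeps normalized values fixed under filtering", {
  cm <- make_cm(matrix(rpois(50, 30), 10))
  sub <- cm_subset(cm, features = c(1, 3, 5))
  expect_equal(sub$normalized, cm$normalized[c(1, 3, 5), , drop = FALSE])
  expect_error(cm_tissue(cm, "brain"), "tissue not present")
})

test_that("YAML threshold configs map onto nc_thresholds", {
  path <- system.file("extdata", "thresholds_example.yaml",
                      package = "ncatlas")
  th <- read_thresholds(path)
  expect_s3_class(th, "nc_thresholds")
  expect_equal(th$min_reads_sample, 2e6)
  expect_equal(th$fc_high, 3 / 2)      # unset keys keep defaults
  ## an override round-trips through a written file
  td <- withr::local_tempdir()
  p2 <- file.path(td, "th.yaml")
  writeLines("rpmm_min: 2.5", p2)
  expect_equal(read_thresholds(p2)$rpmm_min, 2.5)
})
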