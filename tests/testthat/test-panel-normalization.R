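test_that("background correction subtracts the negative-control mean, floored at 1", {
  panel <- tibble::tibble(
    gene_id = c("g1", "g2", "hk", "pos", "n1", "n2"),
    gene_class = c("endogenous", "endogenous", "housekeeping",
                   "positive_control", "negative_control", "negative_control"),
    s1 = c(100, 20, 200, 500, 25, 35)
  )
  out <- background_correct(panel)
  expect_equal(out$s1[out$gene_id == "g1"], 70)   # 100 - mean(25, 35)
  expect_equal(out$s1[out$gene_id == "g2"], 1)    # 20 - 30 floors at 1
  expect_equal(out$s1[out$gene_id == "hk"], 170)
  # controls pass through unchanged
  expect_equal(out$s1[out$gene_id %in% c("pos", "n1", "n2")], c(500, 25, 35))
})

test_that("background correction matches the elementwise max(raw - neg_mean, 1) oracle", {
  panel <- random_panel(n_endo = 50, n_samples = 6, seed = 21)
  out <- background_correct(panel)
  m <- as.matrix(panel[, -(1:2)])
  neg <- panel$gene_class == "negative_control"
  target <- panel$gene_class %in% c("endogenous", "housekeeping")
  expected <- pmax(sweep(m[target, ], 2, colMeans(m[neg, ]), "-"), 1)
  expect_equal(unname(as.matrix(out[target, -(1:2)])), unname(expected))
})

test_that("background correction requires negative controls", {
  panel <- random_panel()
  panel <- panel[panel$gene_class != "negative_control", ]
  expect_error(background_correct(panel), "negative_control")
})

test_that("geomean normalization equalizes control geometric means across samples", {
  panel <- random_panel(seed = 22)
  out <- geomean_normalize(panel)
  m <- as.matrix(out[, -(1:2)])
  hk <- out$gene_class == "housekeeping"
  gm <- apply(m[hk, ], 2, function(x) exp(mean(log(x))))
  expect_equal(max(gm) - min(gm), 0, tolerance = 1e-9)
})

test_that("a sample with half the positive-control geomean is doubled in step 1", {
  base <- c(100, 400, 900, 1600)
  panel <- tibble::tibble(
    gene_id = c("e1", "h1", "h2", sprintf("p%d", 1:4)),
    gene_class = c("endogenous", "housekeeping", "housekeeping", rep("positive_control", 4)),
    s1 = c(50, 80, 80, base), s2 = c(50, 80, 80, base), s3 = c(50, 80, 80, base / 2)
  )
  # cross-sample mean of pos-control geomeans with samples (g, g, g/2): m = 5g/6
  parts <- attr(geomean_normalize(panel), "scale_factors")
  expect_equal(parts$positive_control[3] / parts$positive_control[1], 2)
})

test_that("identical control geomeans leave the matrix unchanged", {
  panel <- tibble::tibble(
    gene_id = c("e1", "e2", "h1", "p1"),
    gene_class = c("endogenous", "endogenous", "housekeeping", "positive_control"),
    s1 = c(10, 20, 50, 100), s2 = c(30, 40, 50, 100)
  )
  out <- geomean_normalize(panel)
  expect_equal(as.matrix(out[, -(1:2)]), as.matrix(panel[, -(1:2)]))
})

test_that("geomean normalization rejects zero control counts", {
  panel <- random_panel()
  panel[panel$gene_class == "housekeeping", "s1"][1, ] <- 0
  expect_error(geomean_normalize(panel), "housekeeping")
})

test_that("scaling one sample's raw counts only rescales the normalized matrix globally", {
  panel <- random_panel(seed = 23)
  scaled <- panel
  scaled$s2 <- scaled$s2 * 3.7
  m1 <- as.matrix(geomean_normalize(panel)[, -(1:2)])
  m2 <- as.matrix(geomean_normalize(scaled)[, -(1:2)])
  ratio <- m2 / m1
  # one global factor: per-sample relative structure is fully preserved
  expect_lt(diff(range(ratio)), 1e-9)
  # and housekeeping geomeans stay equal across samples
  hk <- geomean_normalize(scaled)
  gm <- apply(as.matrix(hk[hk$gene_class == "housekeeping", -(1:2)]), 2,
              function(x) exp(mean(log(x))))
  expect_lt(diff(range(gm)), 1e-9)
})

test_that("quantile normalization has the defining equal-distribution property", {
  # tie-free columns: after normalization every sample carries the identical
  # sorted value vector (tie blocks are averaged and covered by the oracle test)
  panel <- random_panel(seed = 24)
  sample_cols <- setdiff(names(panel), c("gene_id", "gene_class"))
  panel[sample_cols] <- lapply(panel[sample_cols], function(x) x + runif(length(x)))
  norm <- quantile_log2(panel)
  m <- as.matrix(norm[, -1])
  sorted <- apply(m, 2, sort)
  for (j in 2:ncol(sorted)) expect_equal(sorted[, j], sorted[, 1], tolerance = 1e-12)
})

test_that("samples with identical distributions are unchanged up to log2", {
  m <- matrix(c(1, 2, 4, 8, 2, 8, 1, 4), ncol = 2)  # same multiset per column
  qn <- quantile_normalize_matrix(m)
  expect_equal(qn, m)
})

test_that("quantile normalization with ties matches the brute-force oracle", {
  set.seed(25)
  m <- matrix(sample(1:8, 20 * 4, replace = TRUE), nrow = 20)  # many ties
  expect_equal(quantile_normalize_matrix(m), oracle_quantile_norm(m), tolerance = 1e-12)
})

test_that("quantile normalization agrees with limma on tie-free matrices", {
  skip_if_not_installed("limma")
  set.seed(26)
  m <- matrix(rnorm(30 * 5), nrow = 30)
  expect_equal(unname(quantile_normalize_matrix(m)),
               unname(limma::normalizeQuantiles(m)), tolerance = 1e-9)
})

test_that("quantile normalization is idempotent on tie-free matrices", {
  set.seed(27)
  m <- matrix(rnorm(25 * 4), nrow = 25)
  q1 <- quantile_normalize_matrix(m)
  q2 <- quantile_normalize_matrix(q1)
  expect_equal(q2, q1, tolerance = 1e-9)
})

test_that("quantile normalization needs at least two samples", {
  panel <- random_panel(n_samples = 1)
  expect_error(quantile_log2(panel), "2 samples")
})

test_that("the full pipeline runs in the fixed order and records provenance", {
  panel <- random_panel(seed = 28)
  norm <- normalize_panel(panel)
  expect_identical(attr(norm, "provenance"),
                   c("background_correct", "geomean_positive_control",
                     "geomean_housekeeping", "quantile_normalize", "log2"))
  # only endogenous genes remain, no missing values
  expect_equal(nrow(norm), sum(panel$gene_class == "endogenous"))
  expect_false(anyNA(norm))
})
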