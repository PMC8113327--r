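test_that("per-gene ANOVA matches the classical F-test", {
  # identical groups: F = 0, p = 1
  norm <- tibble::tibble(gene_id = "g1", a1 = 1, a2 = 2, a3 = 3, b1 = 1, b2 = 2, b3 = 3)
  res <- anova_per_gene(norm, c("A", "A", "A", "B", "B", "B"))
  expect_equal(res$f_statistic, 0)
  expect_equal(res$p_value, 1)

  # strongly separated groups: p < 1e-10
  set.seed(31)
  x <- c(rnorm(20, 0, 1), rnorm(20, 10, 1))
  norm2 <- dplyr::bind_cols(tibble::tibble(gene_id = "g1"),
                            tibble::as_tibble(as.data.frame(t(x))))
  res2 <- anova_per_gene(norm2, rep(c("A", "B"), each = 20))
  expect_lt(res2$p_value, 1e-10)

  # random matrix against the stats::oneway.test oracle
  set.seed(32)
  m <- matrix(rnorm(20 * 15), nrow = 20)
  g <- rep(c("A", "B", "C"), each = 5)
  norm3 <- dplyr::bind_cols(tibble::tibble(gene_id = sprintf("g%02d", 1:20)),
                            tibble::as_tibble(as.data.frame(m)))
  res3 <- anova_per_gene(norm3, g)
  oracle <- apply(m, 1, function(row) stats::oneway.test(row ~ g, var.equal = TRUE)$p.value)
  expect_equal(res3$p_value, unname(oracle), tolerance = 1e-9)
})

test_that("ANOVA p-values are uniform under the null", {
  set.seed(33)
  m <- matrix(rnorm(1000 * 10), nrow = 1000)
  norm <- dplyr::bind_cols(tibble::tibble(gene_id = sprintf("g%04d", 1:1000)),
                           tibble::as_tibble(as.data.frame(m)))
  res <- anova_per_gene(norm, rep(c("A", "B"), each = 5))
  ks <- stats::ks.test(res$p_value, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("ANOVA validates its grouping", {
  norm <- tibble::tibble(gene_id = "g1", s1 = 1, s2 = 2, s3 = 3)
  expect_error(anova_per_gene(norm, c("A", "A", "A")), "2 groups")
  expect_error(anova_per_gene(norm, c("A", "A", "B")), "2 samples")
})

test_that("BUM fit on pure-uniform p-values estimates pi0 near 1", {
  set.seed(34)
  fit <- fit_bum(runif(5000))
  expect_gte(fit$pi0_hat, 0.95)
})

test_that("BUM fit recovers generating parameters (median over seeds)", {
  ests <- purrr::map_dfr(1:20, function(s) {
    set.seed(100 + s)
    n_sig <- rbinom(1, 5000, 0.4)  # lambda = 0.6 uniform weight
    p <- c(runif(5000 - n_sig), rbeta(n_sig, 0.2, 1))
    fit <- fit_bum(p)
    tibble::tibble(lambda = fit$lambda, a = fit$a)
  })
  expect_lt(abs(median(ests$lambda) - 0.6), 0.05)
  expect_lt(abs(median(ests$a) - 0.2), 0.05)
})

test_that("fitted log-likelihood dominates the generating parameters", {
  set.seed(35)
  p <- c(runif(3000), rbeta(2000, 0.2, 1))
  fit <- fit_bum(p)
  ll_true <- sum(log(0.6 + 0.4 * 0.2 * p^(0.2 - 1)))
  expect_gte(fit$loglik, ll_true)
})

test_that("BUM fit input handling: zeros replaced with warning, bad input errors", {
  set.seed(36)
  expect_warning(fit_bum(c(0, runif(200))), "0 replaced")
  expect_error(fit_bum(c(runif(100), 1.2)), "0, 1")
})

test_that("pure-null fit yields no FDR cutoff", {
  fit <- structure(list(lambda = 1, a = 0.5, pi0_hat = 1, loglik = 0, n = 100),
                   class = "bum_fit")
  expect_true(is.na(bum_fdr_cutoff(fit, 0.001)))
})

test_that("FDR cutoff matches a brute-force grid search", {
  fit <- structure(list(lambda = 0.5, a = 0.1, pi0_hat = 0.5 + 0.5 * 0.1,
                        loglik = 0, n = 1000), class = "bum_fit")
  tau <- bum_fdr_cutoff(fit, 0.001)
  grid <- seq(1e-6, 1, by = 1e-6)
  fdr <- fit$pi0_hat * grid / (fit$lambda * grid + (1 - fit$lambda) * grid^fit$a)
  tau_grid <- max(grid[fdr <= 0.001])
  expect_lt(abs(tau - tau_grid), 1e-6)
  # defining property at the returned cutoff
  bum_fdr_at <- function(t) fit$pi0_hat * t / (fit$lambda * t + (1 - fit$lambda) * t^fit$a)
  expect_lte(bum_fdr_at(tau), 0.001)
  expect_gt(bum_fdr_at(tau + 1e-6), 0.001)
})

test_that("smaller FDR targets never yield larger cutoffs", {
  fit <- structure(list(lambda = 0.6, a = 0.15, pi0_hat = 0.6 + 0.4 * 0.15,
                        loglik = 0, n = 1000), class = "bum_fit")
  taus <- vapply(c(0.05, 0.01, 0.001, 1e-4), function(t) bum_fdr_cutoff(fit, t), numeric(1))
  expect_true(all(diff(taus) <= 0))
})

test_that("the BUM mixture density integrates to 1 over (0, 1]", {
  for (par in list(c(0.2, 0.05), c(0.7, 0.5), c(0.95, 1), c(0, 0.3))) {
    int <- stats::integrate(function(p) par[1] + (1 - par[1]) * par[2] * p^(par[2] - 1),
                            0, 1, rel.tol = 1e-10)
    expect_equal(int$value, 1, tolerance = 1e-6)
  }
})

test_that("DEG selection applies the threshold and sorts by p", {
  pv <- tibble::tibble(gene_id = c("a", "b"), p_value = c(1e-6, 0.5))
  expect_equal(select_degs(pv, 1e-3)$gene_id, "a")
  expect_equal(nrow(select_degs(pv, 1)), 2)
  expect_error(select_degs(pv, NA_real_), "NA")
})

test_that("planted progressive genes are recovered at the BUM-FDR cutoff", {
  recovery <- purrr::map_dbl(1:5, function(s) {
    co <- generate_cohort(small_config(seed = 200 + s, deg_effect = 0.4))
    norm <- normalize_panel(co$expression)
    deg <- stage_degs(norm, as.character(co$samples$stage))
    mean(co$truth$deg_genes %in% deg$selected$gene_id)
  })
  expect_gte(mean(recovery), 0.9)
})

test_that("Fisher enrichment equals the hypergeometric right tail", {
  universe <- sprintf("g%03d", 1:100)
  selected <- universe[1:20]
  sets <- list(
    disjoint = universe[90:95],
    hit = universe[c(1:8, 50, 60)],     # overlap 8, set size 10
    all_selected = selected
  )
  res <- fisher_enrichment(selected, sets, universe)
  expect_equal(res$p_value[res$set == "disjoint"], 1)
  # overlap 8 of set 10, selected 20, universe 100
  expect_equal(res$p_value[res$set == "hit"],
               oracle_fisher_right(8, 10, 20, 100), tolerance = 1e-12)
  # maximal overlap gives the minimal achievable p for that table
  expect_equal(res$p_value[res$set == "all_selected"],
               oracle_fisher_right(20, 20, 20, 100), tolerance = 1e-12)
  expect_error(fisher_enrichment(selected, sets, character(0)), "universe")
  expect_error(fisher_enrichment(c(selected, "not_in_universe"), sets, universe), "subset")
})
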