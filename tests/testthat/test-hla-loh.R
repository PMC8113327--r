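test_that("allele copy numbers invert the purity/ploidy forward model", {
  # diploid heterozygous identity
  cn <- allele_copy_numbers(data.frame(logR = 0, BAF = 0.5), purity = 1, ploidy = 2)
  expect_equal(c(cn$n_a, cn$n_b), c(1, 1))
  # frozen inversion arithmetic: BAF 0.1, logR 0, rho 0.8, psi 2 -> (2, 0)
  cn2 <- allele_copy_numbers(data.frame(logR = 0, BAF = 0.1), purity = 0.8, ploidy = 2)
  expect_equal(c(cn2$n_a, cn2$n_b), c(2, 0), tolerance = 1e-12)
  expect_error(allele_copy_numbers(data.frame(logR = 0, BAF = 0.5), purity = 0, ploidy = 2),
               "purity")
})

test_that("noise-free profiles round-trip the planted copy numbers exactly", {
  for (rho in seq(0.3, 1, by = 0.1)) {
    for (psi in c(1.8, 2, 2.5)) {
      for (planted in list(c(2, 0), c(1, 1), c(3, 1))) {
        prof <- generate_hla_profile(loh = TRUE, purity = rho, ploidy = psi,
                                     n_bins = 5, seed = 1, baf_noise_sd = 0,
                                     logr_noise_sd = 0, allele_cn = planted)
        cn <- allele_copy_numbers(prof, rho, psi)
        expect_equal(cn$n_a, rep(max(planted), 5), tolerance = 1e-9)
        expect_equal(cn$n_b, rep(min(planted), 5), tolerance = 1e-9)
      }
    }
  }
})

test_that("allele copy numbers conserve the logR-implied total", {
  set.seed(41)
  bins <- data.frame(logR = rnorm(20, 0, 0.3), BAF = runif(20))
  rho <- 0.6; psi <- 2.2
  cn <- allele_copy_numbers(bins, rho, psi)
  total_from_logr <- (2^bins$logR * (2 * (1 - rho) + rho * psi) - 2 * (1 - rho)) / rho
  expect_equal(cn$n_a + cn$n_b, total_from_logr, tolerance = 1e-9)
})

test_that("calls are invariant to allele labelling in the input", {
  prof <- generate_hla_profile(TRUE, 0.5, 2, 10, seed = 2)
  flipped <- dplyr::mutate(prof, BAF = 1 - BAF)
  call1 <- call_loh(allele_copy_numbers(prof, 0.5, 2))
  call2 <- call_loh(allele_copy_numbers(flipped, 0.5, 2))
  expect_equal(call1$median_minor_cn, call2$median_minor_cn)
  expect_equal(call1$loh, call2$loh)
})

test_that("LOH requires both median minor CN < 0.5 and p < 0.01", {
  # balanced bins: no LOH
  balanced <- tibble::tibble(n_a = rep(1, 10), n_b = rep(1, 10))
  expect_false(call_loh(balanced)$loh)
  expect_equal(call_loh(balanced)$median_minor_cn, 1)

  # clean loss with tiny jitter: paired t-test oracle, p << 0.01
  set.seed(42)
  jit <- rnorm(10, 0, 1e-3)
  lost <- tibble::tibble(n_a = 2 + jit, n_b = rnorm(10, 0, 1e-3))
  call <- call_loh(lost)
  expect_equal(call$p_value, t.test(lost$n_a, lost$n_b, paired = TRUE)$p.value)
  expect_lt(call$median_minor_cn, 0.5)
  expect_true(call$loh)

  # median < 0.5 but allelic difference too noisy: abstain from LOH
  noisy <- tibble::tibble(n_a = c(3.0, 0.5, 0.6), n_b = c(0.4, 0.45, 0.42))
  p_oracle <- t.test(noisy$n_a, noisy$n_b, paired = TRUE)$p.value
  expect_gt(p_oracle, 0.01)
  call2 <- call_loh(noisy)
  expect_equal(call2$p_value, p_oracle)
  expect_lt(call2$median_minor_cn, 0.5)
  expect_false(call2$loh)
})

test_that("degenerate noise-free differences use the constant-difference convention", {
  loss <- tibble::tibble(n_a = rep(2, 10), n_b = rep(0, 10))
  expect_true(call_loh(loss)$loh)
  expect_equal(call_loh(loss)$p_value, 0)
  flat <- tibble::tibble(n_a = rep(1, 10), n_b = rep(1, 10))
  expect_equal(call_loh(flat)$p_value, 1)
})

test_that("fewer than 3 bins abstains with a reason", {
  call <- call_loh(tibble::tibble(n_a = c(2, 2), n_b = c(0, 0)))
  expect_true(is.na(call$loh))
  expect_match(call$reason, "fewer than 3")
})

test_that("cohort-level calling joins purity and ploidy per sample", {
  bins <- dplyr::bind_rows(
    dplyr::mutate(generate_hla_profile(TRUE, 0.8, 2, 10, seed = 3, baf_noise_sd = 0,
                                       logr_noise_sd = 0),
                  sample_id = "s1", hla_gene = "HLA-A"),
    dplyr::mutate(generate_hla_profile(FALSE, 0.5, 2, 10, seed = 4, baf_noise_sd = 0,
                                       logr_noise_sd = 0),
                  sample_id = "s2", hla_gene = "HLA-A")
  )
  samples <- tibble::tibble(sample_id = c("s1", "s2"), purity = c(0.8, 0.5),
                            ploidy = c(2, 2))
  calls <- call_loh_cohort(bins, samples)
  expect_equal(calls$loh, c(TRUE, FALSE))
})

test_that("stage table reports frequencies and a Pearson chi-square p-value", {
  # no variation: p = 1 with a warning
  calls0 <- tibble::tibble(sample_id = sprintf("s%d", 1:20), hla_gene = "HLA-A",
                           loh = FALSE, n_bins = 10)
  samples0 <- tibble::tibble(sample_id = sprintf("s%d", 1:20),
                             stage = rep(c("AAH", "AIS", "MIA", "ADC"), each = 5))
  expect_warning(res0 <- loh_stage_table(calls0, samples0), "identical")
  expect_equal(res0$p_value, 1)

  # realized table matches a hand-computed Pearson chi-square
  set.seed(43)
  stages <- rep(c("AAH", "AIS", "MIA", "ADC"), each = 200)
  loh <- rbinom(length(stages), 1, c(AAH = 0, AIS = 0.07, MIA = 0.15, ADC = 0.33)[stages]) == 1
  calls <- tibble::tibble(sample_id = sprintf("s%d", seq_along(stages)),
                          hla_gene = "HLA-A", loh = loh, n_bins = 10)
  samples <- tibble::tibble(sample_id = calls$sample_id, stage = stages)
  res <- loh_stage_table(calls, samples)
  tab <- res$table
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  x2 <- sum((tab - expected)^2 / expected)
  p_oracle <- pchisq(x2, df = (nrow(tab) - 1) * (ncol(tab) - 1), lower.tail = FALSE)
  expect_equal(res$p_value, p_oracle, tolerance = 1e-9)
  expect_equal(res$freq$loh_freq,
               as.numeric(tapply(loh, stage_factor(stages), mean)[c("AAH", "AIS", "MIA", "ADC")]))

  # small-sample tables trigger the expected-count warning
  calls1 <- tibble::tibble(sample_id = c("a", "b"), hla_gene = "HLA-A",
                           loh = c(TRUE, FALSE), n_bins = 10)
  samples1 <- tibble::tibble(sample_id = c("a", "b"), stage = c("AAH", "ADC"))
  expect_warning(loh_stage_table(calls1, samples1), "incorrect")
})
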