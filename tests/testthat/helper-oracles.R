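# Independent brute-force oracles used across tests. These deliberately
# avoid the package's own code paths.

oracle_clonality <- function(p) {
  p <- p / sum(p)
  h <- -sum(p * log2(p))
  1 - h / log2(length(p))
}

oracle_inverse_simpson <- function(p) {
  p <- p / sum(p)
  1 / sum(p * p)
}

# rank-partition oracle for the seven fixed top-clone bins
oracle_top_bins <- function(p) {
  p <- sort(p / sum(p), decreasing = TRUE)
  r <- seq_along(p)
  c(sum(p[r == 1]), sum(p[r >= 2 & r <= 10]), sum(p[r >= 11 & r <= 100]),
    sum(p[r >= 101 & r <= 200]), sum(p[r >= 201 & r <= 500]),
    sum(p[r >= 501 & r <= 1000]), sum(p[r > 1000]))
}

# loop-based quantile normalization with mean-of-occupied-ranks ties
oracle_quantile_norm <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    for (i in seq_along(col)) {
      lo <- sum(col < col[i]) + 1
      hi <- sum(col <= col[i])
      out[i, j] <- mean(ref[lo:hi])
    }
  }
  out
}

# hypergeometric right-tail sum for a 2x2 enrichment table
oracle_fisher_right <- function(overlap, set_size, selected, universe) {
  k <- overlap:min(set_size, selected)
  sum(dhyper(k, set_size, universe - set_size, selected))
}

# step-up BH: q_i = min over j >= rank(i) of n * p_(j) / j
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, n * p[o] / seq_len(n))
  for (i in (n - 1):1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  out <- numeric(n)
  out[o] <- q_sorted
  out
}

# Pearson correlation of mid-ranks (Spearman rho with ties)
oracle_spearman_rho <- function(x, y) {
  cor(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
}

# small, fast cohort configuration for tests; ... overrides any default
small_config <- function(seed = 1L, ...) {
  defaults <- list(
    n_per_stage = 8, n_genes = 120, n_housekeeping = 10,
    n_pos_controls = 4, n_neg_controls = 4,
    clone_counts_by_stage = c(NL = 80, AAH = 100, AIS = 120, MIA = 140, ADC = 160),
    promoter_methylation_params = list(
      mean_by_stage = c(NL = 0.15, AAH = 0.19, AIS = 0.23, MIA = 0.27, ADC = 0.31),
      concentration = 8, n_genes = 40),
    n_bins = 10, n_cells = 120, seed = seed
  )
  do.call(cohort_config, utils::modifyList(defaults, list(...)))
}

# random expression panel with all four gene classes
random_panel <- function(n_endo = 50, n_hk = 6, n_pos = 4, n_neg = 3, n_samples = 6,
                         seed = 1) {
  set.seed(seed)
  n <- n_endo + n_hk + n_pos + n_neg
  counts <- matrix(round(runif(n * n_samples, 50, 5000)), nrow = n)
  counts[(n_endo + n_hk + n_pos + 1):n, ] <- round(runif(n_neg * n_samples, 10, 40))
  dplyr::bind_cols(
    tibble::tibble(
      gene_id = sprintf("g%03d", seq_len(n)),
      gene_class = rep(c("endogenous", "housekeeping", "positive_control", "negative_control"),
                       c(n_endo, n_hk, n_pos, n_neg))
    ),
    tibble::as_tibble(structure(as.data.frame(counts), names = paste0("s", seq_len(n_samples))))
  )
}

# brute-force window oracle: number of 9-12-mers inside a protein covering pos
oracle_windows <- function(protein_len, pos, lengths = 9:12) {
  hits <- 0
  for (L in lengths) {
    for (s in 1:(protein_len - L + 1)) {
      if (pos >= s && pos <= s + L - 1) hits <- hits + 1
    }
  }
  hits
}

# one BUM-FDR calibration replicate: fraction of true nulls among selections
simulate_fdp <- function(n_null = 700, n_sig = 300, a_sig = 0.05, fdr_target = 0.001) {
  p <- c(runif(n_null), rbeta(n_sig, a_sig, 1))
  is_null <- rep(c(TRUE, FALSE), c(n_null, n_sig))
  fit <- fit_bum(p)
  tau <- bum_fdr_cutoff(fit, fdr_target)
  if (is.na(tau)) return(0)
  sel <- p <= tau
  if (!any(sel)) return(0)
  mean(is_null[sel])
}
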