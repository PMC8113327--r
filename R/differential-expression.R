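#' Per-gene one-way ANOVA across stages
#'
#' Classical fixed-effects one-way ANOVA F-test applied independently to
#' every gene of a normalized log2 expression table, testing whether the
#' mean expression differs across stage groups. Computed in closed form
#' (between/within sums of squares) for speed; identical to
#' `stats::oneway.test(..., var.equal = TRUE)` gene by gene.
#'
#' When the between-group sum of squares is zero the F statistic is 0 and
#' the p-value 1; a gene with zero variance everywhere (F = 0/0) also
#' reports p = 1 by convention.
#'
#' @param norm Tibble from [quantile_log2()]: `gene_id` plus one numeric
#'   column per sample.
#' @param stages Character or factor vector of group labels, one per sample
#'   column, in column order. Any grouping with >= 2 groups of >= 2 samples
#'   is accepted (the labels need not be histologic stages).
#' @return Tibble with columns `gene_id`, `f_statistic`, `p_value`.
#' @export
anova_per_gene <- function(norm, stages) {
  stopifnot(is.data.frame(norm), "gene_id" %in% names(norm))
  m <- as.matrix(norm[, setdiff(names(norm), "gene_id"), drop = FALSE])
  g <- factor(as.character(stages))
  if (length(g) != ncol(m)) stop("stages must have one label per sample column", call. = FALSE)
  tab <- table(g)
  if (length(tab) < 2) stop("ANOVA requires at least 2 groups", call. = FALSE)
  if (any(tab < 2)) stop("every group needs at least 2 samples", call. = FALSE)
  k <- length(tab)
  n <- ncol(m)
  grand <- rowMeans(m)
  group_means <- vapply(levels(g), function(lv) rowMeans(m[, g == lv, drop = FALSE]), numeric(nrow(m)))
  ss_between <- as.vector(group_means^2 %*% as.vector(tab)) - n * grand^2
  ss_total <- rowSums(m^2) - n * grand^2
  ss_within <- ss_total - ss_between
  f <- (ss_between / (k - 1)) / (ss_within / (n - k))
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  # ss_between ~ 0 (incl. 0/0 degenerate genes) -> F = 0, p = 1
  degenerate <- !is.finite(f) | ss_between <= .Machine$double.eps * pmax(ss_total, 1)
  f[degenerate] <- 0
  p[degenerate] <- 1
  tibble::tibble(gene_id = norm$gene_id, f_statistic = f, p_value = p)
}

# BUM mixture density: lambda + (1 - lambda) * a * p^(a - 1)
bum_density <- function(p, lambda, a) lambda + (1 - lambda) * a * p^(a - 1)

#' Fit a beta-uniform mixture (BUM) model to p-values
#'
#' Models a vector of p-values as a two-component mixture of a uniform null
#' density and a decreasing beta density \eqn{a p^{a-1}} (shape \eqn{a \in
#' (0,1]}) capturing signal concentrated near zero:
#' \deqn{f(p) = \lambda + (1-\lambda)\, a\, p^{a-1}.}
#' Parameters are estimated by maximum likelihood over \eqn{\lambda \in
#' [0,1]}, \eqn{a \in (0,1]} using bounded quasi-Newton optimization from a
#' 3 x 3 grid of starting points; the best converged fit is returned. The
#' estimated upper bound on the null proportion is
#' \eqn{\hat\pi_0 = \lambda + (1-\lambda)a} (the mixture density evaluated
#' at \eqn{p = 1}).
#'
#' @param pvals Numeric vector of p-values in (0, 1]. Zeros are replaced by
#'   the smallest positive double with a warning. At least 100 values are
#'   recommended for a stable fit.
#' @return An object of class `bum_fit`: a list with `lambda`, `a`,
#'   `pi0_hat`, `loglik`, `n`. Has [tidy()] and [glance()] methods.
#' @examples
#' set.seed(1)
#' fit <- fit_bum(c(runif(700), rbeta(300, 0.1, 1)))
#' glance(fit)
#' @export
fit_bum <- function(pvals) {
  stopifnot(is.numeric(pvals), length(pvals) >= 2)
  if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must lie in [0, 1] with no missing values", call. = FALSE)
  }
  if (any(pvals == 0)) {
    warning("p-values equal to 0 replaced by smallest positive double", call. = FALSE)
    pvals[pvals == 0] <- .Machine$double.xmin
  }
  nll <- function(par) -sum(log(bum_density(pvals, par[1], par[2])))
  starts <- expand.grid(lambda = c(0.1, 0.5, 0.9), a = c(0.1, 0.5, 0.9))
  eps <- 1e-9
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(as.numeric(starts[i, ]), nll, method = "L-BFGS-B",
                   lower = c(0, eps), upper = c(1, 1)),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("BUM fit failed to converge from any starting point", call. = FALSE)
  lambda <- best$par[1]
  a <- best$par[2]
  structure(
    list(lambda = lambda, a = a,
         pi0_hat = lambda + (1 - lambda) * a,
         loglik = -best$value, n = length(pvals)),
    class = "bum_fit"
  )
}

#' @export
print.bum_fit <- function(x, ...) {
  cat("Beta-uniform mixture fit (n =", x$n, "p-values)\n")
  cat(sprintf("  lambda = %.4f  a = %.4f  pi0_hat = %.4f  logLik = %.2f\n",
              x$lambda, x$a, x$pi0_hat, x$loglik))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_bum
#' @param x,... A `bum_fit` object; further arguments ignored.
#' @export
tidy.bum_fit <- function(x, ...) {
  tibble::tibble(term = c("lambda", "a"), estimate = c(x$lambda, x$a))
}

#' @rdname fit_bum
#' @export
glance.bum_fit <- function(x, ...) {
  tibble::tibble(pi0_hat = x$pi0_hat, logLik = x$loglik, nobs = x$n)
}

# model-based FDR at cutoff tau under a BUM fit
bum_fdr <- function(fit, tau) {
  f_tau <- fit$lambda * tau + (1 - fit$lambda) * tau^fit$a
  fit$pi0_hat * tau / f_tau
}

#' Derive the p-value cutoff controlling model-based FDR under a BUM fit
#'
#' Under the fitted mixture, the expected false-discovery rate of selecting
#' all p-values at or below \eqn{\tau} is
#' \eqn{\mathrm{FDR}(\tau) = \hat\pi_0 \tau / F(\tau)} with
#' \eqn{F(\tau) = \lambda\tau + (1-\lambda)\tau^a}. For \eqn{a < 1} this is
#' increasing in \eqn{\tau}, so the largest cutoff satisfying
#' \eqn{\mathrm{FDR}(\tau) \le} `fdr_target` is found by bisection. Returns
#' `NA` when no cutoff in (0, 1] attains the target (e.g. a pure-null fit
#' with \eqn{\hat\pi_0 = 1}).
#'
#' @param fit A `bum_fit`.
#' @param fdr_target Nominal FDR in (0, 1); default 0.001 (FDR < 0.1%).
#' @param tol Bisection interval width at termination.
#' @return Scalar cutoff tau in (0, 1], or `NA_real_` when unattainable.
#' @export
bum_fdr_cutoff <- function(fit, fdr_target = 0.001, tol = 1e-10) {
  stopifnot(inherits(fit, "bum_fit"), fdr_target > 0, fdr_target < 1)
  if (bum_fdr(fit, 1) <= fdr_target) return(1)
  # FDR(tau) -> pi0/( (1-lambda)/tau^(1-a)... ) -> 0 as tau -> 0 for a < 1, lambda < 1
  lo <- 0
  hi <- 1
  if (bum_fdr(fit, .Machine$double.xmin) > fdr_target) return(NA_real_)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (bum_fdr(fit, mid) <= fdr_target) lo <- mid else hi <- mid
  }
  if (lo <= 0) NA_real_ else lo
}

#' Select differentially expressed genes at a p-value cutoff
#'
#' @param pvals Tibble from [anova_per_gene()] (columns `gene_id`,
#'   `p_value`) or a named numeric vector.
#' @param tau P-value cutoff, typically from [bum_fdr_cutoff()].
#' @return Tibble of selected genes sorted by ascending p-value.
#' @export
select_degs <- function(pvals, tau) {
  if (is.numeric(pvals)) {
    pvals <- tibble::tibble(gene_id = names(pvals) %||% as.character(seq_along(pvals)),
                            p_value = as.numeric(pvals))
  }
  if (is.na(tau)) stop("no cutoff available (tau is NA)", call. = FALSE)
  pvals |>
    dplyr::filter(.data$p_value <= tau) |>
    dplyr::arrange(.data$p_value)
}

#' Stage-associated differential expression with BUM-derived FDR cutoff
#'
#' Convenience wrapper: per-gene ANOVA p-values, BUM fit, cutoff at
#' `fdr_target`, gene selection.
#'
#' @inheritParams anova_per_gene
#' @inheritParams bum_fdr_cutoff
#' @return List with `pvalues` (tibble), `fit` (`bum_fit`), `tau`,
#'   `selected` (tibble).
#' @export
stage_degs <- function(norm, stages, fdr_target = 0.001) {
  pv <- anova_per_gene(norm, stages)
  fit <- fit_bum(pv$p_value)
  tau <- bum_fdr_cutoff(fit, fdr_target)
  selected <- if (is.na(tau)) pv[0, ] else select_degs(pv, tau)
  list(pvalues = pv, fit = fit, tau = tau, selected = selected)
}

#' Right-tailed Fisher gene-set enrichment
#'
#' For each gene set, tests over-representation of the selected genes with
#' a right-tailed Fisher's exact test on the 2 x 2 table (in set / not in
#' set) x (selected / not selected) over the gene universe, with
#' Benjamini-Hochberg adjustment across sets.
#'
#' @param selected Character vector of selected genes (must be a subset of
#'   `universe`).
#' @param gene_sets Named list of character vectors; each set is intersected
#'   with the universe before testing.
#' @param universe Character vector of all testable genes.
#' @return Tibble with `set`, `set_size`, `overlap`, `odds_ratio`,
#'   `p_value`, `q_value`, sorted by p.
#' @export
fisher_enrichment <- function(selected, gene_sets, universe) {
  if (length(universe) == 0) stop("empty gene universe", call. = FALSE)
  universe <- unique(universe)
  if (!all(selected %in% universe)) stop("selected genes must be a subset of the universe", call. = FALSE)
  res <- purrr::imap(gene_sets, function(set, name) {
    set <- intersect(unique(set), universe)
    overlap <- length(intersect(set, selected))
    tab <- matrix(c(
      overlap, length(set) - overlap,
      length(selected) - overlap,
      length(universe) - length(set) - length(selected) + overlap
    ), nrow = 2)
    ft <- stats::fisher.test(tab, alternative = "greater")
    tibble::tibble(set = name, set_size = length(set), overlap = overlap,
                   odds_ratio = unname(ft$estimate), p_value = ft$p.value)
  })
  dplyr::bind_rows(res) |>
    dplyr::mutate(q_value = stats::p.adjust(.data$p_value, method = "BH")) |>
    dplyr::arrange(.data$p_value)
}
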