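#' Spearman rank correlation between two continuous features
#'
#' Two-sided Spearman rank correlation with mid-rank handling of ties
#' (asymptotic p-value, appropriate in the presence of ties). A constant
#' vector leaves rho undefined; the result is flagged missing rather than
#' erroring.
#'
#' @param x,y Paired numeric vectors (>= 4 finite pairs).
#' @return One-row tibble: `rho`, `p_value`, `n`, `test`.
#' @export
spearman_assoc <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("need at least 4 paired finite values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble::tibble(rho = NA_real_, p_value = NA_real_, n = length(x), test = "spearman"))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x), test = "spearman")
}

#' Compare a continuous feature across groups
#'
#' Dispatches on the number of groups: two levels use the two-sided
#' Wilcoxon rank-sum test (exact when both groups have <= 25 observations
#' and no ties, otherwise the normal approximation with tie correction);
#' more than two levels use the Kruskal-Wallis H test.
#'
#' @param values Numeric vector.
#' @param groups Grouping vector of the same length (>= 2 non-empty
#'   groups).
#' @return One-row tibble: `statistic`, `p_value`, `n_groups`, `test`.
#' @export
group_compare <- function(values, groups) {
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]
  g <- droplevels(factor(groups[ok]))
  k <- nlevels(g)
  if (k < 2) stop("need at least 2 groups", call. = FALSE)
  if (k == 2) {
    a <- values[g == levels(g)[1]]
    b <- values[g == levels(g)[2]]
    exact <- max(length(a), length(b)) <= 25 && !anyDuplicated(values)
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact, correct = TRUE))
    tibble::tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
                   n_groups = 2L, test = "wilcoxon")
  } else {
    kt <- stats::kruskal.test(values, g)
    tibble::tibble(statistic = unname(kt$statistic), p_value = kt$p.value,
                   n_groups = k, test = "kruskal_wallis")
  }
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false discovery rate adjustment (`stats::p.adjust(method =
#' "BH")`).
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values.
#' @export
bh_fdr <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  stats::p.adjust(pvals, method = "BH")
}

#' Copy-number and allelic-imbalance burden of a lesion
#'
#' CNV burden is the percent of assessed genes carrying any copy-number
#' variation; AI burden is the raw count of allelic-imbalance events.
#'
#' @param gene_cnv Logical vector (or 0/1) over assessed genes: gene has a
#'   CNV call.
#' @param ai_events Number of allelic-imbalance events (non-negative
#'   integer), or a vector of event records whose length is counted.
#' @return One-row tibble: `cnv_burden_pct`, `ai_burden`, `n_genes`.
#' @export
cnv_ai_burden <- function(gene_cnv, ai_events) {
  if (length(gene_cnv) == 0) stop("no genes assessed", call. = FALSE)
  cnv <- as.logical(gene_cnv)
  ai <- if (length(ai_events) == 1 && is.numeric(ai_events)) ai_events else length(ai_events)
  tibble::tibble(cnv_burden_pct = 100 * mean(cnv), ai_burden = ai, n_genes = length(cnv))
}

#' Run a planned set of association tests over per-lesion features
#'
#' Applies the dispatch rules of the statistical layer to a plan of feature
#' pairs: continuous vs continuous uses Spearman correlation; continuous
#' vs `stage` (or any categorical feature) uses Wilcoxon/Kruskal-Wallis by
#' level count; binary (logical) vs stage uses the chi-square test.
#' Benjamini-Hochberg adjustment is applied across the executed plan and
#' significance flagged at p < 0.05. Pairs referencing a missing feature
#' are skipped with a warning.
#'
#' @param profiles Per-lesion feature tibble: `sample_id`, `stage`, plus
#'   numeric/logical feature columns.
#' @param plan Data frame with character columns `x` and `y` naming
#'   feature columns (use `"stage"` for the stage label).
#' @return Tibble with `x`, `y`, `test`, `statistic` (rho for Spearman),
#'   `p_value`, `q_value`, `significant`, `direction`.
#' @export
run_association_matrix <- function(profiles, plan) {
  stopifnot(is.data.frame(profiles), all(c("x", "y") %in% names(plan)))
  if (nrow(plan) == 0) {
    return(tibble::tibble(x = character(), y = character(), test = character(),
                          statistic = numeric(), p_value = numeric(),
                          q_value = numeric(), significant = logical(),
                          direction = character()))
  }
  one_pair <- function(xn, yn) {
    if (!xn %in% names(profiles) || !yn %in% names(profiles)) {
      warning("feature pair (", xn, ", ", yn, ") skipped: missing column", call. = FALSE)
      return(NULL)
    }
    x <- profiles[[xn]]
    y <- profiles[[yn]]
    cat_x <- is.factor(x) || is.character(x) || is.logical(x)
    cat_y <- is.factor(y) || is.character(y) || is.logical(y)
    if (!cat_x && !cat_y) {
      res <- spearman_assoc(x, y)
      dir <- if (is.na(res$rho)) NA_character_ else if (res$rho >= 0) "positive" else "negative"
      return(tibble::tibble(x = xn, y = yn, test = res$test, statistic = res$rho,
                            p_value = res$p_value, direction = dir))
    }
    if (cat_x && cat_y) {
      tab <- table(x, y)
      if (min(dim(tab)) < 2) {
        warning("degenerate contingency table for (", xn, ", ", yn, "); p = 1", call. = FALSE)
        return(tibble::tibble(x = xn, y = yn, test = "chi_square", statistic = 0,
                              p_value = 1, direction = NA_character_))
      }
      cs <- suppressWarnings(stats::chisq.test(tab))
      return(tibble::tibble(x = xn, y = yn, test = "chi_square",
                            statistic = unname(cs$statistic), p_value = cs$p.value,
                            direction = NA_character_))
    }
    vals <- if (cat_x) y else x
    grp <- if (cat_x) x else y
    res <- group_compare(vals, grp)
    tibble::tibble(x = xn, y = yn, test = res$test, statistic = res$statistic,
                   p_value = res$p_value, direction = NA_character_)
  }
  out <- purrr::map2(plan$x, plan$y, one_pair) |> dplyr::bind_rows()
  if (nrow(out) == 0) return(out)
  out$q_value <- bh_fdr(out$p_value)
  out$significant <- !is.na(out$p_value) & out$p_value < 0.05
  out
}
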