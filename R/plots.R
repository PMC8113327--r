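#' Stacked top-clone bin composition by sample or stage
#'
#' Mirrors the standard repertoire display: per sample, the share of total
#' productive frequency carried by the top 1, 2-10, 11-100, 101-200,
#' 201-500, 501-1000 and beyond-1000 ranked clones, as a stacked bar chart.
#'
#' @param bin_table Tibble with columns `sample_id`, `bin`, `share`
#'   (e.g. [tcr_top_clone_bins()] applied per sample and row-bound).
#' @return A ggplot object.
#' @export
plot_top_clone_bins <- function(bin_table) {
  stopifnot(all(c("sample_id", "bin", "share") %in% names(bin_table)))
  ggplot2::ggplot(bin_table, ggplot2::aes(x = .data$sample_id, y = .data$share,
                                          fill = .data$bin)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "Dark2", name = "clone rank") +
    ggplot2::labs(x = NULL, y = "share of productive frequency") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, size = 6))
}

#' Stage trend of a per-lesion feature
#'
#' Boxplots of one feature across the ordered stages, with jittered lesion
#' points — the standard display for the stage-trend comparisons tested by
#' Kruskal-Wallis.
#'
#' @param features Per-lesion tibble with a `stage` column.
#' @param feature Name of the feature column to plot.
#' @return A ggplot object.
#' @export
plot_stage_trend <- function(features, feature) {
  stopifnot("stage" %in% names(features), feature %in% names(features))
  ggplot2::ggplot(features, ggplot2::aes(x = .data$stage, y = .data[[feature]])) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = NULL, y = feature) +
    ggplot2::theme_minimal()
}

#' BUM fit diagnostic: p-value histogram with fitted mixture density
#'
#' @param fit A `bum_fit`.
#' @param pvals The p-values the fit was computed from.
#' @param bins Histogram bin count.
#' @return A ggplot object.
#' @export
plot_bum_fit <- function(fit, pvals, bins = 50) {
  stopifnot(inherits(fit, "bum_fit"))
  grid <- tibble::tibble(p = seq(0.001, 1, length.out = 400))
  grid$density <- bum_density(grid$p, fit$lambda, fit$a)
  ggplot2::ggplot(tibble::tibble(p = pvals), ggplot2::aes(x = .data$p)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey85", colour = "grey60") +
    ggplot2::geom_line(data = grid, ggplot2::aes(x = .data$p, y = .data$density),
                       colour = "firebrick") +
    ggplot2::geom_hline(yintercept = fit$pi0_hat, linetype = "dashed") +
    ggplot2::labs(x = "p-value", y = "density",
                  subtitle = sprintf("lambda = %.3f, a = %.3f, pi0 <= %.3f",
                                     fit$lambda, fit$a, fit$pi0_hat)) +
    ggplot2::theme_minimal()
}
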