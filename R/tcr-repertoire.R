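#' TCR-beta repertoire metrics
#'
#' Summary statistics of a T cell receptor beta repertoire, computed on the
#' proportional abundances \eqn{p_i} of productive rearrangements
#' (\eqn{p_i} = productive template count of rearrangement \eqn{i} divided by
#' the total productive template count).
#'
#' * **Clonality** is one minus Pielou's evenness,
#'   \deqn{1 + \frac{\sum_i p_i \log_2 p_i}{\log_2 N},}
#'   where \eqn{N} is the number of rearrangements. It ranges from 0 (all
#'   clones equally frequent, a maximally even repertoire) to values
#'   approaching 1 (a few expanded clones dominate).
#' * **Inverse Simpson diversity** is \eqn{1 / \sum_i p_i^2}; it equals 1 for
#'   a monoclonal repertoire and \eqn{N} for a perfectly even one.
#' * **Density** is the total productive template count divided by the mass
#'   of DNA usable for TCR sequencing, in templates per ng — an estimate of
#'   T cell infiltration.
#'
#' @param repertoire A data frame with one row per rearrangement, containing
#'   at least a `templates` column of positive integer productive template
#'   counts. A `sequence_id` column, when present, is used for deterministic
#'   tie-breaking in ranked summaries. Rows with a `productive` column equal
#'   to `FALSE` are dropped with a message before any computation.
#' @param usable_dna_ng Mass of usable DNA in nanograms (positive scalar).
#' @return A single numeric value.
#' @examples
#' rep <- tibble::tibble(sequence_id = c("a", "b"), templates = c(9L, 1L))
#' tcr_clonality(rep)
#' tcr_inverse_simpson(rep)
#' tcr_density(rep, usable_dna_ng = 0.5)
#' @name tcr_metrics_fns
NULL

# validate and return productive clone table with frequency column
productive_clones <- function(repertoire) {
  stopifnot(is.data.frame(repertoire), "templates" %in% names(repertoire))
  if ("productive" %in% names(repertoire)) {
    n_drop <- sum(!repertoire$productive)
    if (n_drop > 0) {
      message("dropping ", n_drop, " non-productive rearrangement(s)")
      repertoire <- repertoire[repertoire$productive, , drop = FALSE]
    }
  }
  if (nrow(repertoire) < 1) stop("repertoire has no productive rearrangements", call. = FALSE)
  if (any(repertoire$templates <= 0) || any(repertoire$templates != round(repertoire$templates))) {
    stop("template counts must be positive integers", call. = FALSE)
  }
  repertoire$freq <- repertoire$templates / sum(repertoire$templates)
  repertoire
}

#' @rdname tcr_metrics_fns
#' @export
tcr_clonality <- function(repertoire) {
  clones <- productive_clones(repertoire)
  n <- nrow(clones)
  if (n < 2) stop("clonality is undefined for fewer than 2 rearrangements (log2 N = 0)", call. = FALSE)
  p <- clones$freq
  # perfectly even repertoires have evenness exactly 1; avoid returning
  # a floating-point residual for the defining boundary case
  if (all(clones$templates == clones$templates[1])) return(0)
  1 + sum(p * log2(p)) / log2(n)
}

#' @rdname tcr_metrics_fns
#' @export
tcr_inverse_simpson <- function(repertoire) {
  clones <- productive_clones(repertoire)
  1 / sum(clones$freq^2)
}

#' @rdname tcr_metrics_fns
#' @export
tcr_density <- function(repertoire, usable_dna_ng) {
  clones <- productive_clones(repertoire)
  if (!is.numeric(usable_dna_ng) || length(usable_dna_ng) != 1 || usable_dna_ng <= 0) {
    stop("usable_dna_ng must be a positive scalar", call. = FALSE)
  }
  sum(clones$templates) / usable_dna_ng
}

# fixed rank bins used for the top-clone frequency decomposition
tcr_rank_bins <- function() {
  tibble::tibble(
    bin = c("top_1", "top_2_10", "top_11_100", "top_101_200",
            "top_201_500", "top_501_1000", "beyond_1000"),
    lo = c(1, 2, 11, 101, 201, 501, 1001),
    hi = c(1, 10, 100, 200, 500, 1000, Inf)
  )
}

#' Top-clone frequency decomposition
#'
#' Ranks clones by descending frequency (ties broken by `sequence_id` where
#' available, otherwise by input order, so results are deterministic) and
#' aggregates their frequency shares into the seven fixed rank bins used to
#' display repertoire structure: top 1, 2-10, 11-100, 101-200, 201-500,
#' 501-1000 and beyond 1000. The shares always sum to 1.
#'
#' @inheritParams tcr_metrics_fns
#' @return A tibble with columns `bin` (ordered factor) and `share`.
#' @seealso [tcr_top_share()] for the cumulative share of the top k clones.
#' @examples
#' rep <- tibble::tibble(templates = c(40L, 30L, 20L, 5L, 5L))
#' tcr_top_clone_bins(rep)
#' @export
tcr_top_clone_bins <- function(repertoire) {
  clones <- productive_clones(repertoire)
  ord <- if ("sequence_id" %in% names(clones)) {
    order(-clones$freq, clones$sequence_id)
  } else {
    order(-clones$freq)
  }
  p <- clones$freq[ord]
  bins <- tcr_rank_bins()
  rank <- seq_along(p)
  share <- vapply(seq_len(nrow(bins)), function(i) {
    sum(p[rank >= bins$lo[i] & rank <= bins$hi[i]])
  }, numeric(1))
  tibble::tibble(bin = factor(bins$bin, levels = bins$bin), share = share)
}

#' @rdname tcr_top_clone_bins
#' @param k Number of top-ranked clones to aggregate.
#' @return `tcr_top_share()`: the summed frequency of the `k` most frequent
#'   clones (a scalar in (0, 1]).
#' @export
tcr_top_share <- function(repertoire, k = 100) {
  clones <- productive_clones(repertoire)
  ord <- if ("sequence_id" %in% names(clones)) {
    order(-clones$freq, clones$sequence_id)
  } else {
    order(-clones$freq)
  }
  sum(clones$freq[ord][seq_len(min(k, nrow(clones)))])
}

#' Compute all repertoire metrics for a cohort of repertoires
#'
#' Convenience wrapper applying [tcr_clonality()], [tcr_inverse_simpson()],
#' [tcr_density()] and [tcr_top_share()] per sample to a long table of
#' rearrangements.
#'
#' @param rearrangements Data frame with columns `sample_id`, `templates`,
#'   and optionally `sequence_id` / `productive`.
#' @param samples Data frame with columns `sample_id` and `usable_dna_ng`.
#' @param top_k Ranks aggregated by the top-share column (default 100,
#'   matching the headline "frequency of the top 100 T cell clones").
#' @return A tibble with one row per sample: `sample_id`, `n_clones`,
#'   `clonality`, `inverse_simpson`, `density`, `top1_share`, `topk_share`.
#' @export
tcr_metrics <- function(rearrangements, samples, top_k = 100) {
  stopifnot("sample_id" %in% names(rearrangements), "sample_id" %in% names(samples),
            "usable_dna_ng" %in% names(samples))
  rearrangements |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_modify(function(df, key) {
      dna <- samples$usable_dna_ng[match(key$sample_id, samples$sample_id)]
      tibble::tibble(
        n_clones = nrow(productive_clones(df)),
        clonality = tcr_clonality(df),
        inverse_simpson = tcr_inverse_simpson(df),
        density = tcr_density(df, dna),
        top1_share = tcr_top_share(df, 1),
        topk_share = tcr_top_share(df, top_k)
      )
    }) |>
    dplyr::ungroup()
}
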