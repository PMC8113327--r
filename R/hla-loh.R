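#' Allele-specific copy numbers from binned logR/BAF
#'
#' Converts per-bin coverage log-ratios (logR, tumor vs normal) and B-allele
#' fractions (BAF, measured at mismatch positions between the two homologous
#' HLA alleles) into allele-specific copy numbers, adjusting for tumor
#' purity \eqn{\rho} and ploidy \eqn{\psi} (ASCAT-style inversion):
#' \deqn{n_B = \frac{\rho - 1 + \mathrm{BAF}\cdot 2^{\mathrm{logR}}
#'   (2(1-\rho) + \rho\psi)}{\rho}}
#' and symmetrically for \eqn{n_A} with \eqn{1-\mathrm{BAF}}. logR is
#' centred so that logR = 0 corresponds to average tumor ploidy coverage.
#' Noise can push estimates slightly negative; values are reported
#' unclipped. Alleles are relabelled per bin so `n_a >= n_b` (calls are
#' invariant to input allele order).
#'
#' @param bins Data frame with numeric columns `logR` and `BAF` (BAF in
#'   \[0, 1\]), one row per bin.
#' @param purity Tumor purity \eqn{\rho} in (0, 1].
#' @param ploidy Tumor ploidy \eqn{\psi} > 0.
#' @return Input tibble with added columns `n_a` (major) and `n_b` (minor
#'   allele copy number) and `n_total`.
#' @examples
#' allele_copy_numbers(data.frame(logR = 0, BAF = 0.1), purity = 0.8, ploidy = 2)
#' @export
allele_copy_numbers <- function(bins, purity, ploidy) {
  stopifnot(is.data.frame(bins), all(c("logR", "BAF") %in% names(bins)))
  if (!is.numeric(purity) || length(purity) != 1 || purity <= 0 || purity > 1) {
    stop("purity must be a scalar in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(ploidy) || length(ploidy) != 1 || ploidy <= 0) {
    stop("ploidy must be a positive scalar", call. = FALSE)
  }
  if (any(bins$BAF < 0 | bins$BAF > 1)) stop("BAF must lie in [0, 1]", call. = FALSE)
  scale <- 2^bins$logR * (2 * (1 - purity) + purity * ploidy)
  nb <- (purity - 1 + bins$BAF * scale) / purity
  na <- (purity - 1 + (1 - bins$BAF) * scale) / purity
  out <- tibble::as_tibble(bins)
  out$n_a <- pmax(na, nb)
  out$n_b <- pmin(na, nb)
  out$n_total <- na + nb
  out
}

#' Call allele-specific HLA loss of heterozygosity
#'
#' LOH for one HLA gene in one sample is called when the median across bins
#' of the minor-allele copy number is below 0.5 **and** a two-sided paired
#' t-test of per-bin major vs minor copy numbers gives p < 0.01. Fewer than
#' 3 bins yields an abstained call (`loh = NA`) with a reason.
#'
#' When the per-bin allelic difference is numerically constant (noise-free
#' profiles; the paired t-statistic is degenerate) the convention is
#' p = 0 for a nonzero difference and p = 1 for a zero difference.
#'
#' @param cn Tibble from [allele_copy_numbers()] (columns `n_a`, `n_b`).
#' @param median_threshold Minor-allele median copy-number threshold
#'   (default 0.5).
#' @param p_threshold Significance threshold for the allelic-difference
#'   test (default 0.01).
#' @return One-row tibble: `n_bins`, `median_major_cn`, `median_minor_cn`,
#'   `p_value`, `loh` (logical, `NA` when abstained), `reason`.
#' @export
call_loh <- function(cn, median_threshold = 0.5, p_threshold = 0.01) {
  stopifnot(is.data.frame(cn), all(c("n_a", "n_b") %in% names(cn)))
  n <- nrow(cn)
  if (n < 3) {
    return(tibble::tibble(n_bins = n, median_major_cn = NA_real_,
                          median_minor_cn = NA_real_, p_value = NA_real_,
                          loh = NA, reason = "fewer than 3 bins"))
  }
  med_minor <- stats::median(cn$n_b)
  med_major <- stats::median(cn$n_a)
  d <- cn$n_a - cn$n_b
  if (stats::sd(d) < 1e-12) {
    p <- if (abs(mean(d)) > 1e-12) 0 else 1
  } else {
    p <- stats::t.test(cn$n_a, cn$n_b, paired = TRUE)$p.value
  }
  tibble::tibble(
    n_bins = n, median_major_cn = med_major, median_minor_cn = med_minor,
    p_value = p, loh = (med_minor < median_threshold) && (p < p_threshold),
    reason = NA_character_
  )
}

#' Call HLA LOH across a cohort of bin profiles
#'
#' @param bin_table Data frame with columns `sample_id`, `hla_gene`, `logR`,
#'   `BAF` (one row per bin).
#' @param samples Data frame with columns `sample_id`, `purity`, `ploidy`.
#' @inheritParams call_loh
#' @return Tibble with one row per (sample, HLA gene) from [call_loh()].
#' @export
call_loh_cohort <- function(bin_table, samples, median_threshold = 0.5, p_threshold = 0.01) {
  stopifnot(all(c("sample_id", "hla_gene", "logR", "BAF") %in% names(bin_table)),
            all(c("sample_id", "purity", "ploidy") %in% names(samples)))
  bin_table |>
    dplyr::group_by(.data$sample_id, .data$hla_gene) |>
    dplyr::group_modify(function(df, key) {
      i <- match(key$sample_id, samples$sample_id)
      if (is.na(i)) stop("sample ", key$sample_id, " missing from sample table", call. = FALSE)
      call_loh(allele_copy_numbers(df, samples$purity[i], samples$ploidy[i]),
               median_threshold, p_threshold)
    }) |>
    dplyr::ungroup()
}

#' Tabulate lesion-level HLA LOH frequency by stage
#'
#' A lesion counts as LOH-positive when any of its HLA genes is called LOH.
#' Returns the stage-by-LOH contingency table, per-stage frequencies and a
#' Pearson chi-square test of homogeneity. Degenerate tables (no variation
#' in LOH status) report p = 1 with a warning; tables with small expected
#' counts carry the usual chi-square approximation warning.
#'
#' @param calls Tibble from [call_loh_cohort()] (abstained calls are
#'   ignored).
#' @param samples Data frame with `sample_id` and `stage`.
#' @return List with `table` (stage x LOH contingency matrix), `freq`
#'   (tibble of per-stage LOH frequency) and `p_value`.
#' @export
loh_stage_table <- function(calls, samples) {
  stopifnot(all(c("sample_id", "stage") %in% names(samples)))
  lesion <- calls |>
    dplyr::filter(!is.na(.data$loh)) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(loh = any(.data$loh), .groups = "drop") |>
    dplyr::left_join(samples[, c("sample_id", "stage")], by = "sample_id")
  stage <- stage_factor(lesion$stage)
  if (dplyr::n_distinct(stage) < 2) stop("need lesions from at least 2 stages", call. = FALSE)
  tab <- table(stage = droplevels(stage), loh = factor(lesion$loh, levels = c(FALSE, TRUE)))
  freq <- lesion |>
    dplyr::group_by(stage = stage_factor(.data$stage)) |>
    dplyr::summarise(n = dplyr::n(), n_loh = sum(.data$loh),
                     loh_freq = mean(.data$loh), .groups = "drop")
  if (length(unique(lesion$loh)) < 2) {
    warning("LOH status identical across all lesions; p = 1", call. = FALSE)
    p <- 1
  } else {
    p <- stats::chisq.test(tab)$p.value
  }
  list(table = tab, freq = freq, p_value = p)
}
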