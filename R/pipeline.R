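#' Run the full immunogenomic analysis pipeline on a synthetic cohort
#'
#' Orchestrates every module in a fixed order on a generated cohort:
#' panel normalization, stage differential expression with the BUM-derived
#' FDR cutoff, TCR repertoire metrics, mIF phenotype percentages, HLA LOH
#' calling and the stage table, neoantigen counts with the
#' promoter-methylation filter, and the planned association tests over the
#' assembled per-lesion feature table. All randomness flows from the
#' config seed, so two runs with the same config are identical.
#'
#' @param config A [cohort_config()].
#' @param fdr_target FDR target for DEG selection (default 0.001).
#' @param association_plan Optional data frame of feature pairs (columns
#'   `x`, `y`) for [run_association_matrix()]; `NULL` uses a default plan
#'   covering the planted stage trends and cross-feature correlations.
#' @param out_dir Optional directory; when given, per-module outputs and a
#'   JSON manifest are written there as TSV/JSON.
#' @return Object of class `ipn_pipeline`: list with `cohort`,
#'   `normalized`, `deg`, `tcr`, `phenotypes`, `loh`, `neoantigen`
#'   (per-lesion counts), `features` (per-lesion feature table),
#'   `associations`, `summary` (per-stage means) and `manifest`.
#' @export
run_pipeline <- function(config = cohort_config(), fdr_target = 0.001,
                         association_plan = NULL, out_dir = NULL) {
  steps <- character()
  note <- function(s) steps <<- c(steps, s)

  cohort <- generate_cohort(config); note("generate_cohort")
  normalized <- normalize_panel(cohort$expression); note("normalize_panel")
  deg <- stage_degs(normalized, as.character(cohort$samples$stage), fdr_target)
  note("stage_degs")
  tcr <- tcr_metrics(cohort$rearrangements, cohort$samples); note("tcr_metrics")

  pheno <- cohort$cells |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_modify(function(df, key) {
      cell_percentages(assign_phenotypes(df), nrow(df))
    }) |>
    dplyr::ungroup() |>
    tidyr::pivot_wider(id_cols = "sample_id", names_from = "phenotype",
                       values_from = "percent", names_prefix = "pct_")
  note("assign_phenotypes")

  loh_calls <- call_loh_cohort(cohort$hla_bins, cohort$samples)
  loh_table <- loh_stage_table(loh_calls, cohort$samples)
  note("call_loh_cohort")

  neo <- if (nrow(cohort$mutations) > 0 && nrow(cohort$peptide_scores) > 0) {
    scored <- binding_filter(cohort$peptide_scores)
    cohort$mutations |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::group_modify(function(df, key) {
        pm <- cohort$promoter_meth[cohort$promoter_meth$sample_id == key$sample_id, ]
        suppressWarnings(neoantigen_mutation_counts(df, scored, pm))
      }) |>
      dplyr::ungroup()
  } else {
    tibble::tibble(sample_id = character(), n_neoantigen_mutations = integer(),
                   n_unmethylated_neoantigen_mutations = integer())
  }
  note("neoantigen_mutation_counts")

  hyper <- cohort$promoter_meth |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(hypermeth_gene_frac = hypermethylated_gene_fraction(
      dplyr::pick(dplyr::everything())), .groups = "drop")

  lesion_loh <- loh_calls |>
    dplyr::filter(!is.na(.data$loh)) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(hla_loh = any(.data$loh), .groups = "drop")

  features <- cohort$samples |>
    dplyr::left_join(tcr, by = "sample_id") |>
    dplyr::left_join(pheno, by = "sample_id") |>
    dplyr::left_join(lesion_loh, by = "sample_id") |>
    dplyr::left_join(hyper, by = "sample_id") |>
    dplyr::left_join(neo, by = "sample_id") |>
    dplyr::mutate(
      n_neoantigen_mutations = dplyr::coalesce(.data$n_neoantigen_mutations, 0L),
      n_unmethylated_neoantigen_mutations = dplyr::coalesce(.data$n_unmethylated_neoantigen_mutations, 0L),
      treg_ctl_ratio = phenotype_ratio(.data$pct_treg, .data$pct_ctl)
    )
  note("assemble_features")

  plan <- association_plan %||% tibble::tibble(
    x = c("clonality", "top1_share", "topk_share", "density", "inverse_simpson",
          "global_methylation", "hypermeth_gene_frac", "hla_loh",
          "global_methylation", "global_methylation", "global_methylation",
          "pct_treg", "pct_ctl"),
    y = c("stage", "stage", "stage", "stage", "stage",
          "stage", "stage", "stage",
          "ai_burden", "cnv_burden_pct", "pct_treg",
          "stage", "stage")
  )
  associations <- run_association_matrix(features, plan); note("run_association_matrix")

  summary <- features |>
    dplyr::group_by(.data$stage) |>
    dplyr::summarise(
      n = dplyr::n(),
      clonality = mean(.data$clonality),
      top1_share = mean(.data$top1_share),
      topk_share = mean(.data$topk_share),
      density = mean(.data$density),
      loh_freq = mean(dplyr::coalesce(.data$hla_loh, FALSE)),
      hypermeth_gene_frac = mean(.data$hypermeth_gene_frac),
      global_methylation = mean(.data$global_methylation),
      pct_treg = mean(.data$pct_treg),
      pct_ctl = mean(.data$pct_ctl),
      .groups = "drop"
    )
  note("summarise")

  manifest <- list(
    package_version = as.character(utils::packageVersion("ipnimmune")),
    seed = config$seed,
    fdr_target = fdr_target,
    n_deg_selected = nrow(deg$selected),
    steps = steps
  )

  result <- structure(
    list(cohort = cohort, normalized = normalized, deg = deg, tcr = tcr,
         phenotypes = pheno, loh = list(calls = loh_calls, stage_table = loh_table),
         neoantigen = neo, features = features, associations = associations,
         summary = summary, manifest = manifest),
    class = "ipn_pipeline"
  )

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_tsv(features, file.path(out_dir, "features.tsv"))
    readr::write_tsv(associations, file.path(out_dir, "associations.tsv"))
    readr::write_tsv(summary, file.path(out_dir, "stage_summary.tsv"))
    readr::write_tsv(deg$pvalues, file.path(out_dir, "deg_pvalues.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}

#' @export
print.ipn_pipeline <- function(x, ...) {
  cat("Immunogenomic pipeline run (seed", x$manifest$seed, ")\n")
  cat("  DEGs selected:", x$manifest$n_deg_selected,
      "at tau =", format(x$deg$tau, digits = 3), "\n")
  cat("  Stage summary:\n")
  print(as.data.frame(x$summary), digits = 3, row.names = FALSE)
  invisible(x)
}
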