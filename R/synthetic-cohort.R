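#' Configuration for the synthetic multi-stage cohort generator
#'
#' Builds and validates the parameter set for [generate_cohort()]. Defaults
#' encode the study conditions the downstream analyses assume: five ordered
#' histologic stages (NL, AAH, AIS, MIA, ADC); an immune panel of 730
#' endogenous genes, 40 housekeeping genes, 6 positive controls and 8
#' negative controls; a fraction of endogenous genes whose log2 expression
#' shifts monotonically with stage index; TCR repertoires drawn from a
#' stick-breaking law whose concentration increases with stage (so the
#' expected top-clone share and clonality decrease); lesion-level HLA LOH
#' planted at per-stage rates 0, 0, 7, 15, 33%; mutation counts increasing
#' with stage; promoter methylation increasing and global (LINE-1-like)
#' methylation decreasing with stage; and a shared latent chromosomal
#' instability variable that ties AI/CNV burden and Treg infiltration
#' negatively to global methylation.
#'
#' @param n_per_stage Lesions per stage.
#' @param n_genes,n_housekeeping,n_pos_controls,n_neg_controls Panel shape.
#' @param deg_fraction Fraction of endogenous genes with a planted
#'   progressive stage effect.
#' @param deg_effect Per-stage-step log2 expression shift of planted genes.
#' @param expression_noise_sd Log2-scale gene-level noise sd.
#' @param clone_counts_by_stage Named integer vector (stages in order):
#'   repertoire sizes.
#' @param top_clone_decay Named numeric vector: stick-breaking concentration
#'   per stage (larger = more even repertoire).
#' @param loh_rate_by_stage Named probabilities of lesion-level HLA LOH.
#' @param purity_range,ploidy_range Uniform sampling ranges for tumor
#'   purity and ploidy.
#' @param mutation_rate_by_stage Named Poisson means for per-lesion mutation
#'   counts.
#' @param promoter_methylation_params List: `mean_by_stage` (per-stage mean
#'   promoter CpG-methylated fraction), `concentration` (beta precision),
#'   `n_genes` (genes profiled per lesion).
#' @param global_methylation_trend List: `base`, `stage_slope`, `cin_coef`
#'   (loading of the latent instability variable), `sd` (residual noise).
#' @param n_bins Bins per HLA gene profile.
#' @param baf_noise_sd,logr_noise_sd Gaussian noise sds on emitted BAF
#'   (truncated to \[0, 1\]) and logR.
#' @param n_cells Cells per lesion in the simulated mIF table.
#' @param seed Integer seed; all randomness derives from it through
#'   per-block substreams, so regenerating with the same config is
#'   bit-identical and adding a feature block never perturbs earlier ones.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_stage = 50,
                          n_genes = 730,
                          n_housekeeping = 40,
                          n_pos_controls = 6,
                          n_neg_controls = 8,
                          deg_fraction = 0.25,
                          deg_effect = 0.25,
                          expression_noise_sd = 0.4,
                          clone_counts_by_stage = c(NL = 800, AAH = 1000, AIS = 1200, MIA = 1400, ADC = 1600),
                          top_clone_decay = c(NL = 8, AAH = 15, AIS = 25, MIA = 40, ADC = 60),
                          loh_rate_by_stage = c(NL = 0, AAH = 0, AIS = 0.07, MIA = 0.15, ADC = 0.33),
                          purity_range = c(0.3, 0.7),
                          ploidy_range = c(1.8, 2.5),
                          mutation_rate_by_stage = c(NL = 0.5, AAH = 3, AIS = 6, MIA = 10, ADC = 15),
                          promoter_methylation_params = list(
                            mean_by_stage = c(NL = 0.15, AAH = 0.19, AIS = 0.23, MIA = 0.27, ADC = 0.31),
                            concentration = 8, n_genes = 200),
                          global_methylation_trend = list(
                            base = 0.78, stage_slope = -0.025, cin_coef = -0.04, sd = 0.01),
                          n_bins = 30,
                          baf_noise_sd = 0.03,
                          logr_noise_sd = 0.08,
                          n_cells = 400,
                          seed = 1L) {
  cfg <- structure(as.list(environment()), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  fail <- function(field, msg) {
    stop("invalid cohort configuration: field '", field, "' ", msg, call. = FALSE)
  }
  count_fields <- c("n_per_stage", "n_genes", "n_housekeeping", "n_pos_controls",
                    "n_neg_controls", "n_bins", "n_cells")
  for (f in count_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 1 || v != round(v)) fail(f, "must be a positive integer")
  }
  if (cfg$n_bins < 3) fail("n_bins", "must be at least 3 for LOH calling")
  for (f in c("deg_fraction")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1) fail(f, "must lie in [0, 1]")
  }
  for (f in c("clone_counts_by_stage", "top_clone_decay", "loh_rate_by_stage",
              "mutation_rate_by_stage")) {
    v <- cfg[[f]]
    if (length(v) != 5 || !identical(names(v), stage_levels())) {
      fail(f, "must be a vector named by the five stages in order")
    }
  }
  if (any(cfg$loh_rate_by_stage < 0 | cfg$loh_rate_by_stage > 1)) {
    fail("loh_rate_by_stage", "probabilities must lie in [0, 1]")
  }
  if (any(cfg$clone_counts_by_stage < 2)) fail("clone_counts_by_stage", "clone counts must be >= 2")
  if (any(cfg$top_clone_decay <= 0)) fail("top_clone_decay", "concentrations must be positive")
  for (f in c("purity_range", "ploidy_range")) {
    v <- cfg[[f]]
    if (length(v) != 2 || v[1] > v[2]) fail(f, "must be an increasing pair")
  }
  if (cfg$purity_range[1] <= 0 || cfg$purity_range[2] > 1) fail("purity_range", "must lie in (0, 1]")
  pm <- cfg$promoter_methylation_params
  if (any(pm$mean_by_stage <= 0 | pm$mean_by_stage >= 1)) {
    fail("promoter_methylation_params", "mean_by_stage must lie in (0, 1)")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1) fail("seed", "must be a single integer")
  invisible(cfg)
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# vectorized random amino-acid strings
random_aa <- function(n, len) {
  m <- matrix(sample(AA20, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m))
}

#' Simulate one TCR repertoire for a given stage
#'
#' Clone frequencies follow a stick-breaking (GEM) law with the stage's
#' concentration parameter from `top_clone_decay`: stick fractions are
#' Beta(1, alpha) so small alpha concentrates mass on the first sticks
#' (high top-clone share, early stages) and large alpha spreads it (late
#' stages). Productive template counts are a multinomial draw of the
#' total template count over the stick weights; clones receiving zero
#' templates are dropped, as a sequenced repertoire never reports
#' zero-template rearrangements.
#'
#' @param stage Stage label.
#' @param config A [cohort_config()].
#' @param seed Integer seed for this repertoire.
#' @param total_templates Total productive templates to distribute
#'   (default drawn around 1500).
#' @return Tibble with `sequence_id`, `junction_aa`, `productive`,
#'   `templates`.
#' @export
generate_repertoire <- function(stage, config = cohort_config(), seed = 1L,
                                total_templates = NULL) {
  stage <- as.character(stage_factor(stage))
  k <- config$clone_counts_by_stage[[stage]]
  if (k < 2) stop("clone count must be >= 2 (clonality undefined otherwise)", call. = FALSE)
  alpha <- config$top_clone_decay[[stage]]
  withr::with_seed(seed, {
    v <- stats::rbeta(k, 1, alpha)
    w <- v * cumprod(c(1, 1 - v[-k]))
    w <- w / sum(w)
    total <- total_templates %||% (1000 + stats::rpois(1, 500))
    counts <- as.vector(stats::rmultinom(1, total, w))
    keep <- counts > 0
    tibble::tibble(
      sequence_id = sprintf("clone%05d", seq_len(k))[keep],
      junction_aa = paste0("CASS", random_aa(sum(keep), 6), "F"),
      productive = TRUE,
      templates = counts[keep]
    )
  })
}

#' Simulate a binned logR/BAF profile for one HLA gene
#'
#' Forward model: with planted allele copy numbers \eqn{(n_A, n_B)},
#' purity \eqn{\rho} and ploidy \eqn{\psi},
#' \deqn{\mathrm{BAF} = \frac{\rho n_B + (1-\rho)}{\rho(n_A+n_B) + 2(1-\rho)},
#'   \quad \mathrm{logR} = \log_2\frac{\rho(n_A+n_B) + 2(1-\rho)}
#'   {\rho\psi + 2(1-\rho)},}
#' i.e. logR is centred on average tumor ploidy coverage. Gaussian noise is
#' added per bin (BAF truncated to \[0, 1\]). LOH plants \eqn{(2, 0)} by
#' default; the balanced state is \eqn{(1, 1)}.
#'
#' @param loh Logical: plant allele loss.
#' @param purity Tumor purity in (0, 1].
#' @param ploidy Tumor ploidy (> 0).
#' @param n_bins Number of bins (>= 3).
#' @param seed Integer seed.
#' @param baf_noise_sd,logr_noise_sd Noise sds (0 for noise-free bins).
#' @param allele_cn Length-2 planted copy numbers used when `loh = TRUE`
#'   (default `c(2, 0)`).
#' @return Tibble with `bin_index`, `logR`, `BAF` and the planted `n_a`,
#'   `n_b` as attributes `planted_cn`.
#' @export
generate_hla_profile <- function(loh, purity, ploidy = 2, n_bins = 30, seed = 1L,
                                 baf_noise_sd = 0.03, logr_noise_sd = 0.08,
                                 allele_cn = c(2, 0)) {
  if (!is.numeric(purity) || purity <= 0 || purity > 1) {
    stop("purity must lie in (0, 1]", call. = FALSE)
  }
  if (n_bins < 3) stop("n_bins must be at least 3", call. = FALSE)
  cn <- if (isTRUE(loh)) allele_cn else c(1, 1)
  na <- max(cn); nb <- min(cn)
  total <- purity * (na + nb) + 2 * (1 - purity)
  denom <- purity * ploidy + 2 * (1 - purity)
  baf_clean <- (purity * nb + (1 - purity)) / total
  logr_clean <- log2(total / denom)
  withr::with_seed(seed, {
    baf <- baf_clean + stats::rnorm(n_bins, 0, baf_noise_sd)
    logr <- logr_clean + stats::rnorm(n_bins, 0, logr_noise_sd)
  })
  out <- tibble::tibble(
    bin_index = seq_len(n_bins),
    logR = logr,
    BAF = pmin(pmax(baf, 0), 1)
  )
  attr(out, "planted_cn") <- c(n_a = na, n_b = nb)
  out
}

#' Generate a seeded synthetic multi-stage cohort
#'
#' Draws a full cohort of lesions across the five stages with every feature
#' block the downstream modules consume: a raw expression panel with
#' planted progressive differential expression, per-lesion TCR repertoires,
#' HLA bin profiles with planted LOH at stage-dependent rates, mutation
#' tables with peptide-level binding scores, promoter and global
#' methylation, AI/CNV burdens, and per-cell mIF marker calls. A latent
#' per-lesion chromosomal-instability variable couples global
#' hypomethylation to AI/CNV burden and Treg infiltration, planting the
#' cross-feature correlations the association layer is expected to
#' recover. Regeneration with the same config (including seed) is
#' bit-identical.
#'
#' @param config A [cohort_config()].
#' @return Object of class `synthetic_cohort`: a list of tibbles
#'   (`samples`, `expression`, `rearrangements`, `hla_bins`, `mutations`,
#'   `peptide_scores`, `promoter_meth`, `cells`), a `truth` list of planted
#'   parameters, and the `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  seed <- config$seed
  stages <- rep(stage_levels(), each = config$n_per_stage)
  n <- length(stages)
  idx <- stage_index(stages)
  ids <- sprintf("S%03d_%s", seq_len(n), stages)

  # --- sample-level block: purity, ploidy, latent instability, methylation, burdens
  samples <- withr::with_seed(sub_seed(seed, 1), {
    z <- stats::rnorm(n)
    cin <- 0.5 * idx + z
    gmt <- config$global_methylation_trend
    gm <- gmt$base + gmt$stage_slope * idx + gmt$cin_coef * z + stats::rnorm(n, 0, gmt$sd)
    tibble::tibble(
      sample_id = ids,
      stage = stage_factor(stages),
      purity = stats::runif(n, config$purity_range[1], config$purity_range[2]),
      ploidy = stats::runif(n, config$ploidy_range[1], config$ploidy_range[2]),
      usable_dna_ng = stats::runif(n, 20, 80),
      cin = cin,
      global_methylation = pmin(pmax(gm, 0), 1),
      ai_burden = stats::rpois(n, exp(1.0 + 0.3 * cin)),
      cnv_burden_pct = 100 * stats::plogis(-1.5 + 0.4 * cin + stats::rnorm(n, 0, 0.3)),
      loh_planted = stats::rbinom(n, 1, config$loh_rate_by_stage[stages]) == 1
    )
  })

  # --- expression panel block
  expression <- withr::with_seed(sub_seed(seed, 2), {
    n_deg <- round(config$deg_fraction * config$n_genes)
    gene_ids <- c(sprintf("GENE%04d", seq_len(config$n_genes)),
                  sprintf("HK%02d", seq_len(config$n_housekeeping)),
                  sprintf("POS%d", seq_len(config$n_pos_controls)),
                  sprintf("NEG%d", seq_len(config$n_neg_controls)))
    gene_class <- rep(panel_classes, c(config$n_genes, config$n_housekeeping,
                                       config$n_pos_controls, config$n_neg_controls))
    mu <- c(stats::rnorm(config$n_genes, 8, 1.5),
            stats::rnorm(config$n_housekeeping, 10, 0.8),
            seq(6, 16, length.out = config$n_pos_controls),
            rep(NA_real_, config$n_neg_controls))
    deg_dir <- numeric(config$n_genes)
    deg_dir[seq_len(n_deg)] <- sample(c(-1, 1), n_deg, replace = TRUE)
    scale_s <- exp(stats::rnorm(n, 0, 0.25))
    bg_s <- stats::runif(n, 20, 40)
    shift <- outer(c(deg_dir, rep(0, length(gene_ids) - config$n_genes)), idx) * config$deg_effect
    noise <- matrix(stats::rnorm(length(gene_ids) * n, 0, config$expression_noise_sd),
                    nrow = length(gene_ids))
    log2_true <- mu + shift + noise
    counts <- sweep(2^log2_true, 2, scale_s, "*")
    neg <- gene_class == "negative_control"
    counts[neg, ] <- 0
    counts <- round(counts + matrix(stats::rpois(length(gene_ids) * n, rep(bg_s, each = length(gene_ids))),
                                    nrow = length(gene_ids)))
    panel <- dplyr::bind_cols(
      tibble::tibble(gene_id = gene_ids, gene_class = gene_class),
      tibble::as_tibble(structure(as.data.frame(counts), names = ids))
    )
    list(panel = panel, deg_genes = gene_ids[seq_len(n_deg)],
         deg_direction = deg_dir[seq_len(n_deg)])
  })

  # --- TCR repertoire block (one substream per lesion)
  rearrangements <- purrr::map(seq_len(n), function(i) {
    dens <- max(5, 40 + 10 * idx[i] + withr::with_seed(sub_seed(seed, 1000 + i), stats::rnorm(1, 0, 5)))
    total <- max(10L, as.integer(round(samples$usable_dna_ng[i] * dens)))
    rep <- generate_repertoire(stages[i], config, seed = sub_seed(seed, 2000 + i),
                               total_templates = total)
    rep$sample_id <- ids[i]
    rep
  }) |> dplyr::bind_rows()

  # --- HLA bin block
  hla_genes <- c("HLA-A", "HLA-B", "HLA-C")
  hla_bins <- purrr::map(seq_len(n), function(i) {
    lost_gene <- if (samples$loh_planted[i]) {
      withr::with_seed(sub_seed(seed, 3000 + i), sample(hla_genes, 1))
    } else NA_character_
    purrr::map(seq_along(hla_genes), function(j) {
      prof <- generate_hla_profile(
        loh = identical(hla_genes[j], lost_gene),
        purity = samples$purity[i], ploidy = samples$ploidy[i],
        n_bins = config$n_bins, seed = sub_seed(seed, 4000 + i * 10 + j),
        baf_noise_sd = config$baf_noise_sd, logr_noise_sd = config$logr_noise_sd
      )
      prof$sample_id <- ids[i]
      prof$hla_gene <- hla_genes[j]
      prof
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  # --- mutation + peptide block
  mut_blocks <- withr::with_seed(sub_seed(seed, 5), {
    endo_genes <- expression$panel$gene_id[expression$panel$gene_class == "endogenous"]
    n_mut <- stats::rpois(n, config$mutation_rate_by_stage[stages])
    muts <- purrr::map(seq_len(n), function(i) {
      if (n_mut[i] == 0) return(NULL)
      ctx <- random_aa(n_mut[i], 25)
      ref <- substr(ctx, 13, 13)
      alt <- vapply(ref, function(r) sample(setdiff(AA20, r), 1), character(1))
      tibble::tibble(
        mutation_id = sprintf("%s_mut%02d", ids[i], seq_len(n_mut[i])),
        sample_id = ids[i],
        gene = sample(endo_genes, n_mut[i], replace = TRUE),
        type = sample(c("missense", "stop_gain"), n_mut[i], replace = TRUE, prob = c(0.9, 0.1)),
        pos = 13L, ref = unname(ref), alt = unname(alt), context = ctx
      )
    }) |> dplyr::bind_rows()
    peptides <- NULL
    if (nrow(muts) > 0) {
      mis <- muts[muts$type == "missense", , drop = FALSE]
      peptides <- purrr::map(seq_len(nrow(mis)), function(k) {
        pep <- enumerate_mutant_peptides(mis$context[k], mis$pos[k], mis$ref[k], mis$alt[k])
        pep$mutation_id <- mis$mutation_id[k]
        pep
      }) |> dplyr::bind_rows()
      if (nrow(peptides) > 0) {
        mut_mu <- stats::runif(nrow(mis), 2, 5.5)
        peptides$ic50_nM <- 10^(mut_mu[match(peptides$mutation_id, mis$mutation_id)] +
                                  stats::rnorm(nrow(peptides), 0, 0.3))
        peptides$rank_pct <- pmin(100, (peptides$ic50_nM / 500) * 2 *
                                    exp(stats::rnorm(nrow(peptides), 0, 0.5)))
      }
    }
    list(mutations = muts, peptides = peptides %||% tibble::tibble())
  })

  # --- promoter methylation block
  pm <- config$promoter_methylation_params
  promoter_meth <- withr::with_seed(sub_seed(seed, 6), {
    meth_genes <- expression$panel$gene_id[expression$panel$gene_class == "endogenous"][seq_len(pm$n_genes)]
    mu_m <- pm$mean_by_stage[stages]
    purrr::map(seq_len(n), function(i) {
      tibble::tibble(
        sample_id = ids[i],
        gene = meth_genes,
        promoter_meth_frac = stats::rbeta(pm$n_genes, mu_m[i] * pm$concentration,
                                          (1 - mu_m[i]) * pm$concentration)
      )
    }) |> dplyr::bind_rows()
  })

  # --- mIF cell block
  cells <- withr::with_seed(sub_seed(seed, 7), {
    p_treg <- stats::plogis(-2.5 + 0.25 * samples$cin)
    purrr::map(seq_len(n), function(i) {
      nc <- config$n_cells
      cd3 <- stats::runif(nc) < 0.30
      cd8 <- cd3 & stats::runif(nc) < (0.55 - 0.05 * idx[i])
      cd4like <- cd3 & !cd8
      gzmb <- (cd8 & stats::runif(nc) < (0.50 - 0.06 * idx[i])) |
        (cd4like & stats::runif(nc) < pmax(0.02, 0.10 - 0.015 * idx[i]))
      foxp3 <- (cd4like & stats::runif(nc) < p_treg[i]) | (!cd3 & stats::runif(nc) < 0.005)
      tibble::tibble(
        sample_id = ids[i],
        cell_id = sprintf("%s_c%04d", ids[i], seq_len(nc)),
        ck = !cd3 & stats::runif(nc) < 0.35,
        cd3 = cd3, cd8 = cd8, gzmb = gzmb, foxp3 = foxp3,
        cd68 = !cd3 & stats::runif(nc) < 0.08,
        pd1 = cd3 & stats::runif(nc) < 0.15,
        pdl1 = stats::runif(nc) < 0.05,
        cd45ro = cd3 & stats::runif(nc) < 0.4,
        compartment = sample(c("epithelial", "stroma"), nc, replace = TRUE),
        panel = 2L
      )
    }) |> dplyr::bind_rows()
  })

  structure(
    list(
      samples = dplyr::select(samples, -"cin"),
      expression = expression$panel,
      rearrangements = rearrangements,
      hla_bins = hla_bins,
      mutations = mut_blocks$mutations,
      peptide_scores = mut_blocks$peptides,
      promoter_meth = promoter_meth,
      cells = cells,
      truth = list(deg_genes = expression$deg_genes,
                   deg_direction = expression$deg_direction,
                   loh_planted = stats::setNames(samples$loh_planted, ids),
                   cin = stats::setNames(samples$cin, ids)),
      config = config
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic multi-stage cohort:", nrow(x$samples), "lesions (",
      x$config$n_per_stage, "per stage ), seed", x$config$seed, "\n")
  cat("  feature blocks: expression (", nrow(x$expression), "genes ),",
      "TCR (", nrow(x$rearrangements), "rearrangements ),",
      "HLA bins, mutations (", nrow(x$mutations), "),",
      "promoter/global methylation, mIF cells\n")
  invisible(x)
}

#' Write a synthetic cohort to a directory of TSV files
#'
#' One TSV per feature block plus a JSON manifest recording the
#' configuration and seed, so a run can be reproduced or the files consumed
#' by external tools.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  blocks <- c("samples", "expression", "rearrangements", "hla_bins",
              "mutations", "peptide_scores", "promoter_meth", "cells")
  for (b in blocks) {
    readr::write_tsv(cohort[[b]], file.path(dir, paste0(b, ".tsv")))
  }
  cfg <- cohort$config
  cfg_json <- lapply(unclass(cfg), function(v) if (is.list(v)) v else unname(v))
  jsonlite::write_json(list(config = cfg_json, seed = cfg$seed),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
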