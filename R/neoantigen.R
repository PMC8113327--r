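#' Enumerate mutant 9-12-mer peptides spanning a missense mutation
#'
#' For a missense mutation, extracts every peptide window of length 9, 10,
#' 11 and 12 that lies fully inside the mutant protein sequence and
#' contains the mutated position; duplicate sequences are removed. A
#' mutation at least 11 residues from both termini with no duplicated
#' windows yields 9 + 10 + 11 + 12 = 42 candidates. Stop-gain mutations
#' truncate the protein without introducing novel residues, so they yield
#' zero candidate peptides (with a warning).
#'
#' @param context Protein sequence (single string of one-letter amino-acid
#'   codes) surrounding the mutation — ideally >= 11 residues each side.
#' @param pos 1-based position of the mutated residue within `context`.
#' @param ref,alt Reference and alternate one-letter residues; `context`
#'   may carry either at `pos` (the reference is substituted by `alt`).
#' @param type `"missense"` or `"stop_gain"`.
#' @param lengths Peptide lengths to enumerate (default 9:12).
#' @return Tibble with columns `peptide`, `length`, `mut_offset` (1-based
#'   position of the mutant residue within the peptide).
#' @examples
#' enumerate_mutant_peptides(strrep("A", 25), pos = 13, ref = "A", alt = "V")
#' @export
enumerate_mutant_peptides <- function(context, pos, ref, alt, type = "missense",
                                      lengths = 9:12) {
  stopifnot(is.character(context), length(context) == 1)
  type <- match.arg(type, c("missense", "stop_gain"))
  if (type == "stop_gain") {
    warning("stop-gain mutations introduce no novel residues; 0 candidate peptides",
            call. = FALSE)
    return(tibble::tibble(peptide = character(), length = integer(), mut_offset = integer()))
  }
  aa <- strsplit(context, "")[[1]]
  if (pos < 1 || pos > length(aa)) stop("mutation position outside context sequence", call. = FALSE)
  if (identical(ref, alt)) stop("alternate residue equals reference: not a missense mutation", call. = FALSE)
  aa[pos] <- alt
  out <- purrr::map(lengths, function(L) {
    starts <- max(1, pos - L + 1):min(pos, length(aa) - L + 1)
    starts <- starts[starts >= 1 & starts + L - 1 <= length(aa)]
    if (length(starts) == 0) return(NULL)
    tibble::tibble(
      peptide = vapply(starts, function(s) paste(aa[s:(s + L - 1)], collapse = ""), character(1)),
      length = L,
      mut_offset = pos - starts + 1L
    )
  })
  dplyr::bind_rows(out) |> dplyr::distinct(.data$peptide, .keep_all = TRUE)
}

#' Flag MHC-binding peptides by affinity or rank threshold
#'
#' A candidate peptide is a predicted binder when its predicted affinity
#' IC50 is below 500 nM **or** its percentile rank score is below 2%
#' (strict inequalities; a peptide at exactly IC50 = 500 or rank = 2 is not
#' a binder). The same rule applies to MHC class I and class II
#' predictions. Candidates missing both scores are dropped with a warning.
#'
#' @param candidates Data frame with numeric columns `ic50_nM` and/or
#'   `rank_pct` (NA allowed in one of them per row).
#' @param ic50_threshold,rank_threshold Binding thresholds (defaults
#'   500 nM and 2%).
#' @return Input tibble with a logical `binder` column; rows missing both
#'   scores removed.
#' @export
binding_filter <- function(candidates, ic50_threshold = 500, rank_threshold = 2) {
  stopifnot(is.data.frame(candidates))
  if (!any(c("ic50_nM", "rank_pct") %in% names(candidates))) {
    stop("candidates need an ic50_nM and/or rank_pct column", call. = FALSE)
  }
  out <- tibble::as_tibble(candidates)
  if (!"ic50_nM" %in% names(out)) out$ic50_nM <- NA_real_
  if (!"rank_pct" %in% names(out)) out$rank_pct <- NA_real_
  if (any(out$ic50_nM <= 0, na.rm = TRUE)) stop("ic50_nM must be positive", call. = FALSE)
  if (any(out$rank_pct < 0 | out$rank_pct > 100, na.rm = TRUE)) {
    stop("rank_pct must lie in [0, 100]", call. = FALSE)
  }
  missing_both <- is.na(out$ic50_nM) & is.na(out$rank_pct)
  if (any(missing_both)) {
    warning(sum(missing_both), " candidate(s) missing both scores dropped", call. = FALSE)
    out <- out[!missing_both, , drop = FALSE]
  }
  out$binder <- (!is.na(out$ic50_nM) & out$ic50_nM < ic50_threshold) |
    (!is.na(out$rank_pct) & out$rank_pct < rank_threshold)
  out
}

#' Count neoantigen-associated mutations, with promoter-methylation filter
#'
#' A mutation is *neoantigen-associated* when at least one of its candidate
#' peptides passes the binding filter. The second count retains only
#' neoantigen-associated mutations whose source gene's promoter is not
#' hypermethylated (promoter CpG-methylated fraction <= 0.30; a fraction
#' strictly above 30% defines hypermethylation and silences the gene).
#' Mutations in genes absent from the methylation table contribute to the
#' first count but are excluded from the second, with a warning.
#'
#' @param mutations Data frame with columns `mutation_id` and `gene`.
#' @param candidates Data frame with `mutation_id` and a logical `binder`
#'   column (from [binding_filter()]).
#' @param promoter_meth Data frame with `gene` and `promoter_meth_frac` in
#'   \[0, 1\].
#' @param hyper_threshold Hypermethylation threshold (default 0.30,
#'   exclusive).
#' @return One-row tibble: `n_neoantigen_mutations`,
#'   `n_unmethylated_neoantigen_mutations`.
#' @export
neoantigen_mutation_counts <- function(mutations, candidates, promoter_meth,
                                       hyper_threshold = 0.30) {
  stopifnot(all(c("mutation_id", "gene") %in% names(mutations)),
            all(c("mutation_id", "binder") %in% names(candidates)),
            all(c("gene", "promoter_meth_frac") %in% names(promoter_meth)))
  binder_muts <- unique(candidates$mutation_id[candidates$binder])
  neo <- mutations[mutations$mutation_id %in% binder_muts, , drop = FALSE]
  meth <- promoter_meth$promoter_meth_frac[match(neo$gene, promoter_meth$gene)]
  if (any(is.na(meth)) && nrow(neo) > 0) {
    warning(sum(is.na(meth)), " neoantigen mutation(s) in genes absent from the ",
            "methylation table excluded from the unmethylated count", call. = FALSE)
  }
  tibble::tibble(
    n_neoantigen_mutations = nrow(neo),
    n_unmethylated_neoantigen_mutations = sum(!is.na(meth) & meth <= hyper_threshold)
  )
}

#' Fraction of genes with promoter hypermethylation
#'
#' Share of genes whose promoter CpG-methylated fraction exceeds 30%
#' (strictly).
#'
#' @inheritParams neoantigen_mutation_counts
#' @return Scalar fraction in \[0, 1\].
#' @export
hypermethylated_gene_fraction <- function(promoter_meth, hyper_threshold = 0.30) {
  stopifnot("promoter_meth_frac" %in% names(promoter_meth))
  f <- promoter_meth$promoter_meth_frac
  if (length(f) == 0) stop("methylation table has no genes", call. = FALSE)
  if (any(f < 0 | f > 1)) stop("promoter_meth_frac must lie in [0, 1]", call. = FALSE)
  mean(f > hyper_threshold)
}
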