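#' Default multiplex-immunofluorescence phenotype gates
#'
#' Named boolean gate expressions over per-cell marker calls. Defaults:
#' total T = CD3+; CD8 T = CD3+CD8+; CTL = CD3+CD8+GZMB+;
#' ThCTL = CD3+CD8-GZMB+; Treg = CD3+CD8-FoxP3+; the CD4 compartment is
#' represented by CD3+CD8- (direct CD4 staining is unreliable in mIF;
#' double-negative contamination is acknowledged, not corrected).
#'
#' @return Named character vector of gate expressions referencing marker
#'   column names.
#' @export
default_phenotype_map <- function() {
  c(
    total_t = "cd3",
    cd8_t = "cd3 & cd8",
    ctl = "cd3 & cd8 & gzmb",
    thctl = "cd3 & !cd8 & gzmb",
    treg = "cd3 & !cd8 & foxp3",
    cd4_t = "cd3 & !cd8"
  )
}

#' Assign mIF phenotypes to cells and count them
#'
#' Evaluates each gate expression against the logical marker columns of a
#' per-cell table (every row is one DAPI-identified nucleated cell). A cell
#' may satisfy several gates (e.g. a CD3+CD8+GZMB+ cell counts as CTL, CD8
#' T and total T). Counts are reported per phenotype, optionally per
#' compartment.
#'
#' @param cells Data frame with one row per nucleated cell and logical
#'   marker columns (e.g. `cd3`, `cd8`, `gzmb`, `foxp3`); an optional
#'   `compartment` column splits counts.
#' @param map Named character vector of gate expressions (default
#'   [default_phenotype_map()]). Referencing a marker absent from the table
#'   is an error.
#' @param by_compartment Split counts by the `compartment` column.
#' @return Tibble with `phenotype`, optional `compartment`, and `count`.
#' @export
assign_phenotypes <- function(cells, map = default_phenotype_map(), by_compartment = FALSE) {
  stopifnot(is.data.frame(cells), length(map) > 0, !is.null(names(map)))
  markers <- names(cells)[vapply(cells, is.logical, logical(1))]
  flags <- purrr::imap(map, function(expr_str, name) {
    expr <- str2lang(expr_str)
    used <- all.vars(expr)
    missing <- setdiff(used, markers)
    if (length(missing) > 0) {
      stop("gate '", name, "' references marker(s) absent from the panel: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    eval(expr, envir = cells)
  })
  out <- purrr::imap(flags, function(flag, name) {
    if (by_compartment) {
      if (!"compartment" %in% names(cells)) stop("cells lack a compartment column", call. = FALSE)
      tibble::tibble(phenotype = name, compartment = cells$compartment, hit = flag) |>
        dplyr::group_by(.data$phenotype, .data$compartment) |>
        dplyr::summarise(count = sum(.data$hit), .groups = "drop")
    } else {
      tibble::tibble(phenotype = name, count = sum(flag))
    }
  })
  dplyr::bind_rows(out)
}

#' Phenotype abundance as percent of nucleated cells
#'
#' @param counts Tibble from [assign_phenotypes()] (columns `phenotype`,
#'   `count`).
#' @param total_nucleated Total number of nucleated cells on the panel
#'   (must be >= every count).
#' @return Input tibble with a `percent` column (100 * count / total).
#' @export
cell_percentages <- function(counts, total_nucleated) {
  stopifnot(all(c("phenotype", "count") %in% names(counts)))
  if (!is.numeric(total_nucleated) || length(total_nucleated) != 1 || total_nucleated <= 0) {
    stop("total_nucleated must be a positive scalar", call. = FALSE)
  }
  if (any(counts$count > total_nucleated)) {
    stop("phenotype count exceeds total nucleated cells", call. = FALSE)
  }
  dplyr::mutate(tibble::as_tibble(counts), percent = 100 * .data$count / total_nucleated)
}

#' Marker-signature score per sample
#'
#' Unweighted mean of normalized log2 expression over a set of marker
#' genes, per sample — e.g. the Th1 signature as the average of IFNG,
#' IL12A and IL12B. Markers absent from the matrix are skipped with a
#' message; no marker present is an error.
#'
#' @param norm Normalized expression tibble (`gene_id` + sample columns),
#'   as returned by [quantile_log2()].
#' @param markers Character vector of marker gene ids.
#' @param name Signature name recorded in the output.
#' @return Tibble with `sample_id`, `signature`, `score`.
#' @export
signature_score <- function(norm, markers, name = "signature") {
  stopifnot("gene_id" %in% names(norm))
  present <- intersect(markers, norm$gene_id)
  absent <- setdiff(markers, norm$gene_id)
  if (length(absent) > 0) message("marker(s) absent from matrix skipped: ", paste(absent, collapse = ", "))
  if (length(present) == 0) stop("none of the signature markers are present in the matrix", call. = FALSE)
  m <- as.matrix(norm[match(present, norm$gene_id), setdiff(names(norm), "gene_id"), drop = FALSE])
  tibble::tibble(sample_id = colnames(m), signature = name, score = unname(colMeans(m)))
}

#' Ratio of two per-sample abundances
#'
#' Elementwise ratio of two abundance vectors (e.g. Treg% / CTL%,
#' Th2/Th1 score). For count-derived percentages a pseudocount is added to
#' numerator and denominator to keep ratios defined at zero; for
#' signature scores (already positive) use `pseudocount = 0`. When both
#' terms are zero and no pseudocount is used the ratio is `NA`.
#'
#' @param numerator,denominator Numeric vectors of equal length.
#' @param pseudocount Value added to both terms (default 0.01 percentage
#'   points).
#' @return Numeric vector of ratios with attribute `pseudocount`.
#' @export
phenotype_ratio <- function(numerator, denominator, pseudocount = 0.01) {
  stopifnot(length(numerator) == length(denominator))
  num <- numerator + pseudocount
  den <- denominator + pseudocount
  out <- ifelse(den == 0, NA_real_, num / den)
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Default T-helper polarization marker sets
#'
#' Th1 markers (IFNG, IL12A, IL12B) follow the signature used for the Th1
#' axis; the Th2 and Th17 sets are configurable package defaults
#' (canonical lineage cytokines/factors), flagged as an assumption in the
#' output of any score built from them.
#'
#' @return Named list of character vectors.
#' @export
default_th_signatures <- function() {
  list(
    th1 = c("IFNG", "IL12A", "IL12B"),
    th2 = c("IL4", "IL5", "IL13"),
    th17 = c("IL17A", "IL17F", "RORC")
  )
}
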