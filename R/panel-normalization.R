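#' Immune expression panel normalization
#'
#' Raw immune-panel counts (nCounter-style) are normalized in a fixed
#' sequence: negative-control background correction, two-step
#' geometric-mean scaling (positive controls, then housekeeping genes),
#' quantile normalization of the endogenous genes, and a log2 transform for
#' variance stabilization. Each step is a separate function so intermediate
#' matrices can be inspected; [normalize_panel()] chains them in the fixed
#' order and records the executed sequence in the `provenance` attribute of
#' the result.
#'
#' A *panel* is a tibble with columns `gene_id`, `gene_class` (one of
#' `endogenous`, `housekeeping`, `positive_control`, `negative_control`) and
#' one numeric column of non-negative counts per sample.
#'
#' @param panel Panel tibble as described above.
#' @return A panel tibble of the same shape (counts replaced by corrected or
#'   scaled values), with the `provenance` attribute extended.
#' @name panel_normalization
NULL

panel_classes <- c("endogenous", "housekeeping", "positive_control", "negative_control")

# split panel into gene metadata and numeric count matrix
panel_parts <- function(panel) {
  stopifnot(is.data.frame(panel), all(c("gene_id", "gene_class") %in% names(panel)))
  bad <- setdiff(unique(panel$gene_class), panel_classes)
  if (length(bad) > 0) stop("unknown gene_class value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (anyDuplicated(panel$gene_id)) stop("gene_id values must be unique", call. = FALSE)
  sample_cols <- setdiff(names(panel), c("gene_id", "gene_class"))
  if (length(sample_cols) < 1) stop("panel has no sample columns", call. = FALSE)
  m <- as.matrix(panel[, sample_cols, drop = FALSE])
  if (!is.numeric(m)) stop("sample columns must be numeric", call. = FALSE)
  if (any(m < 0)) stop("counts must be non-negative", call. = FALSE)
  list(meta = panel[, c("gene_id", "gene_class")], counts = m, samples = sample_cols)
}

panel_rebuild <- function(parts, counts, panel, step) {
  out <- dplyr::bind_cols(parts$meta, tibble::as_tibble(counts))
  attr(out, "provenance") <- c(attr(panel, "provenance"), step)
  out
}

#' @describeIn panel_normalization Subtract, per sample, the mean of the
#'   negative-control counts from every endogenous and housekeeping gene,
#'   flooring corrected counts at 1 so geometric means and log2 stay
#'   defined. Control genes pass through unchanged (positive controls are
#'   still needed by the next step). Errors when no negative controls are
#'   present.
#' @export
background_correct <- function(panel) {
  parts <- panel_parts(panel)
  neg <- parts$meta$gene_class == "negative_control"
  if (!any(neg)) stop("background correction requires at least one negative_control gene", call. = FALSE)
  bg <- colMeans(parts$counts[neg, , drop = FALSE])
  target <- parts$meta$gene_class %in% c("endogenous", "housekeeping")
  counts <- parts$counts
  counts[target, ] <- pmax(sweep(counts[target, , drop = FALSE], 2, bg, "-"), 1)
  panel_rebuild(parts, counts, panel, "background_correct")
}

# one geometric-mean scaling pass on the given control class
geomean_step <- function(parts, counts, class) {
  ctrl <- parts$meta$gene_class == class
  if (!any(ctrl)) stop("geomean normalization requires ", class, " genes", call. = FALSE)
  if (any(counts[ctrl, ] <= 0)) {
    stop("zero or negative count among ", class, " genes; geometric mean undefined", call. = FALSE)
  }
  gm <- apply(counts[ctrl, , drop = FALSE], 2, geomean)
  factors <- unname(mean(gm) / gm)
  if (any(factors < 0.1 | factors > 10)) {
    warning("scale factor outside [0.1, 10] in ", class, " normalization", call. = FALSE)
  }
  list(counts = sweep(counts, 2, factors, "*"), factors = factors)
}

#' @describeIn panel_normalization Two-step content normalization: each
#'   sample is scaled so its positive-control geometric mean matches the
#'   cross-sample mean of positive-control geometric means, then again using
#'   the housekeeping genes. Per-sample scale factors are recorded in
#'   provenance; factors outside \[0.1, 10\] trigger a warning.
#' @export
geomean_normalize <- function(panel) {
  parts <- panel_parts(panel)
  s1 <- geomean_step(parts, parts$counts, "positive_control")
  s2 <- geomean_step(parts, s1$counts, "housekeeping")
  out <- panel_rebuild(parts, s2$counts, panel,
                       c("geomean_positive_control", "geomean_housekeeping"))
  attr(out, "scale_factors") <- tibble::tibble(
    sample_id = parts$samples, positive_control = s1$factors, housekeeping = s2$factors
  )
  out
}

#' Classic quantile normalization of a numeric matrix
#'
#' Each column is sorted, sorted values are replaced by the across-column
#' mean at each rank, and the original order restored. Tied values within a
#' column receive the mean of the reference values at their tied ranks, so
#' the procedure is deterministic and idempotent.
#'
#' @param m Numeric matrix (rows = genes, columns = samples), >= 2 columns.
#' @return Matrix of the same dimensions with identical marginal
#'   distributions across columns.
#' @export
quantile_normalize_matrix <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (ncol(m) < 2) stop("quantile normalization requires at least 2 samples", call. = FALSE)
  ref <- rowMeans(apply(m, 2, sort))
  apply(m, 2, function(col) {
    r_min <- rank(col, ties.method = "min")
    r_max <- rank(col, ties.method = "max")
    # a tie block occupies a run of ranks; all members get the mean of the
    # reference values over that run
    vapply(seq_along(col), function(i) mean(ref[r_min[i]:r_max[i]]), numeric(1))
  })
}

#' @describeIn panel_normalization Quantile-normalize the endogenous genes
#'   (controls and housekeeping genes are excluded from this global
#'   adjustment) and apply log2. Returns a tibble of `gene_id` plus one
#'   column per sample of log2 values, with the full `provenance` attribute.
#' @export
quantile_log2 <- function(panel) {
  parts <- panel_parts(panel)
  endo <- parts$meta$gene_class == "endogenous"
  if (!any(endo)) stop("no endogenous genes in panel", call. = FALSE)
  m <- parts$counts[endo, , drop = FALSE]
  if (any(m <= 0)) stop("endogenous counts must be positive before log2", call. = FALSE)
  qn <- quantile_normalize_matrix(m)
  out <- dplyr::bind_cols(
    tibble::tibble(gene_id = parts$meta$gene_id[endo]),
    tibble::as_tibble(log2(qn))
  )
  attr(out, "provenance") <- c(attr(panel, "provenance"), "quantile_normalize", "log2")
  out
}

#' @describeIn panel_normalization Run the full fixed pipeline:
#'   `background_correct` then `geomean_normalize` (positive controls, then
#'   housekeeping) then `quantile_log2`.
#' @export
normalize_panel <- function(panel) {
  panel |> background_correct() |> geomean_normalize() |> quantile_log2()
}
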