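#' Ordered histologic stages of early lung adenocarcinoma
#'
#' The analysis spans five ordered histologic stages: matched normal lung
#' (`NL`), atypical adenomatous hyperplasia (`AAH`, preneoplasia),
#' adenocarcinoma in situ (`AIS`, preinvasive), minimally invasive
#' adenocarcinoma (`MIA`) and frankly invasive adenocarcinoma (`ADC`).
#' `stage_levels()` returns the canonical level order; `stage_factor()`
#' coerces a vector to an ordered factor on those levels and errors on
#' unknown labels.
#'
#' @param x Character or factor vector of stage labels.
#' @return `stage_levels()`: character vector of length 5.
#'   `stage_factor()`: ordered factor. `stage_index()`: integer 0-4.
#' @examples
#' stage_factor(c("NL", "ADC", "AIS"))
#' stage_index("MIA")
#' @export
stage_levels <- function() c("NL", "AAH", "AIS", "MIA", "ADC")

#' @rdname stage_levels
#' @export
stage_factor <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), stage_levels())
  if (length(bad) > 0) {
    stop("unknown stage label(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(stage_levels(), collapse = ", "),
         call. = FALSE)
  }
  factor(x, levels = stage_levels(), ordered = TRUE)
}

#' @rdname stage_levels
#' @export
stage_index <- function(x) as.integer(stage_factor(x)) - 1L

# geometric mean of strictly positive values
geomean <- function(x) exp(mean(log(x)))

# derive a reproducible 32-bit sub-seed from a base seed and block offset
sub_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset * 16807) %% 2147483647)
}
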