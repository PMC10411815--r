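#' Feature-by-subject matrix for one omics layer on one chromosome
#'
#' The basic data container of the pipeline: an \eqn{N_k \times M} numeric
#' matrix of feature values \eqn{x_{i_k j k}} for one omics layer \eqn{k}
#' (gene expression, DNA methylation or genomic variants) restricted to one
#' chromosome, together with its feature and subject identifiers.
#'
#' @param values numeric matrix, features in rows, subjects in columns. No
#'   missing values are allowed; preprocessing (binning, genotype encoding
#'   with imputation) is expected to have removed them.
#' @param layer character scalar naming the omics layer, conventionally one
#'   of `"expression"`, `"methylation"` or `"variant"`. For the variant
#'   layer all values must be dosages in \[0, 2\].
#' @param chrom chromosome label, e.g. `"chr1"`.
#' @param feature_ids,subject_ids optional identifier vectors; default to
#'   the dimnames of `values` (generated if absent).
#'
#' @return An object of class `omics_matrix`: a list with elements
#'   `values`, `layer`, `chrom`, `feature_ids`, `subject_ids`.
#' @export
#' @examples
#' om <- omics_matrix(matrix(1:6, 3, 2), layer = "expression", chrom = "chr1")
#' dim(om)
omics_matrix <- function(values, layer, chrom,
                         feature_ids = NULL, subject_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L)
    stop("omics_matrix needs at least one feature (N_k >= 1)")
  if (ncol(values) < 2L)
    stop("omics_matrix needs at least two subjects (M >= 2)")
  if (anyNA(values) || any(!is.finite(values)))
    stop("omics_matrix values must be finite and non-missing")
  stopifnot(is.character(layer) || is.factor(layer), length(layer) == 1L,
            length(chrom) == 1L)
  layer <- as.character(layer)
  if (is.null(feature_ids))
    feature_ids <- rownames(values) %||% paste0("f", seq_len(nrow(values)))
  if (is.null(subject_ids))
    subject_ids <- colnames(values) %||% paste0("S", seq_len(ncol(values)))
  if (length(feature_ids) != nrow(values))
    stop("feature_ids length does not match the number of rows")
  if (length(subject_ids) != ncol(values))
    stop("subject_ids length does not match the number of columns")
  if (anyDuplicated(subject_ids))
    stop("subject_ids must be unique")
  if (identical(layer, "variant") &&
      (min(values) < 0 || max(values) > 2))
    stop("variant-layer values must be dosages in [0, 2]")
  dimnames(values) <- list(feature_ids, subject_ids)
  structure(
    list(values = values, layer = layer, chrom = as.character(chrom),
         feature_ids = as.character(feature_ids),
         subject_ids = as.character(subject_ids)),
    class = "omics_matrix"
  )
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix: %s / %s, %d features x %d subjects\n",
              x$layer, x$chrom, nrow(x$values), ncol(x$values)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## all layers entering one kernel tensor must describe the same subjects in
## the same order
check_shared_subjects <- function(layers) {
  stopifnot(length(layers) >= 1L)
  ref <- layers[[1L]]$subject_ids
  for (om in layers[-1L]) {
    if (!identical(om$subject_ids, ref))
      stop("subject_ids differ across layers: all omics layers must share ",
           "the same subjects in the same order")
  }
  ref
}
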