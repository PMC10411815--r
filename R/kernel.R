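#' Build the subject-pair kernel tensor for one chromosome
#'
#' For each omics layer \eqn{k} with feature matrix \eqn{x_{i_k j k}}
#' (features \eqn{i_k}, subjects \eqn{j}), forms the linear-kernel slice
#' \deqn{x_{j j' k} = \sum_{i_k = 1}^{N_k} x_{i_k j k}\, x_{i_k j' k}}
#' and stacks the \eqn{K} slices into an \eqn{M \times M \times K} tensor.
#' Features enter raw (no centering or scaling), so with non-negative
#' signals the leading subject factor of the decomposition captures the
#' overall mean level. Each slice is computed by streaming over feature
#' blocks, so a variant layer with millions of rows never needs more than
#' one block resident.
#'
#' @param layers list of [omics_matrix()] objects sharing the same
#'   subjects in the same order (one per omics layer).
#' @param standardize if `TRUE`, each feature row is centered and scaled
#'   to unit variance before entering the kernel (off by default: the
#'   kernel is defined on raw values).
#' @param block_size number of feature rows per streaming block.
#'
#' @return A `kernel_tensor`: an M x M x K array with attributes
#'   `subject_ids` and `layers`. Every slice is symmetric and positive
#'   semi-definite.
#' @export
#' @examples
#' om <- omics_matrix(matrix(1, 1, 2), "expression", "chr1")
#' build_kernel_tensor(list(om))[, , 1]
build_kernel_tensor <- function(layers, standardize = FALSE,
                                block_size = 65536L) {
  subject_ids <- check_shared_subjects(layers)
  M <- length(subject_ids)
  K <- length(layers)
  layer_names <- vapply(layers, function(om) om$layer, character(1L))
  if (anyDuplicated(layer_names))
    layer_names <- make.unique(layer_names)
  arr <- array(0, dim = c(M, M, K),
               dimnames = list(subject_ids, subject_ids, layer_names))
  for (k in seq_len(K)) {
    X <- layers[[k]]$values
    if (standardize) {
      mu <- rowMeans(X)
      sd_ <- apply(X, 1L, stats::sd)
      sd_[sd_ == 0] <- 1
      X <- (X - mu) / sd_
    }
    N <- nrow(X)
    S <- matrix(0, M, M)
    for (from in seq(1L, N, by = block_size)) {
      to <- min(from + block_size - 1L, N)
      S <- S + crossprod(X[from:to, , drop = FALSE])
    }
    arr[, , k] <- (S + t(S)) / 2  # enforce exact symmetry
  }
  structure(arr, class = "kernel_tensor",
            subject_ids = subject_ids, layers = layer_names)
}

#' @export
print.kernel_tensor <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("kernel_tensor: %d x %d subjects x %d layers (%s)\n",
              d[1], d[2], d[3],
              paste(attr(x, "layers"), collapse = ", ")))
  invisible(x)
}
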