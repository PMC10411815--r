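#' Higher-order SVD of a subject-pair kernel tensor
#'
#' Decomposes an \eqn{M \times M \times K} kernel tensor as
#' \deqn{x_{j j' k} = \sum_{\ell_1}\sum_{\ell_2}\sum_{\ell_3}
#'   G(\ell_1 \ell_2 \ell_3)\, u_{\ell_1 j}\, u_{\ell_2 j'}\, u_{\ell_3 k}}
#' where the subject-mode factor matrix \eqn{u_{\ell_1 j}} holds the left
#' singular vectors of the mode-1 unfolding (an \eqn{M \times MK} matrix),
#' the omics-mode factor \eqn{u_{\ell_3 k}} holds those of the mode-3
#' unfolding (\eqn{K \times M^2}), and the core tensor G is the input
#' contracted with the factor transposes on every mode. Because the first
#' two modes are symmetric, a single SVD serves both subject modes.
#'
#' Each factor column's sign is fixed so that its largest-magnitude entry
#' is positive (first occurrence wins on ties), making the output
#' deterministic; all downstream correlation-based selection is invariant
#' to these sign choices.
#'
#' @param tensor a `kernel_tensor` from [build_kernel_tensor()], or any
#'   M x M x K array whose slices are symmetric in the first two modes.
#'
#' @return An object of class `hosvd_factors`: list with `core`
#'   (M x M x K array), `subject_factors` (M x M orthonormal, columns are
#'   \eqn{u_{\ell_1 j}}), `omics_factors` (K x K orthonormal), the
#'   mode-1 and mode-3 singular values, and the subject/layer labels.
#' @export
#' @examples
#' om <- omics_matrix(matrix(rnorm(20), 5, 4), "expression", "chr1")
#' f <- hosvd(build_kernel_tensor(list(om)))
#' crossprod(f$subject_factors)[1:2, 1:2]  # identity
hosvd <- function(tensor) {
  a <- unclass(tensor)
  stopifnot(is.array(a), length(dim(a)) == 3L)
  d <- dim(a)
  if (d[1L] != d[2L])
    stop("tensor must be M x M x K (symmetric subject modes)")
  if (any(!is.finite(a))) stop("tensor contains non-finite entries")
  M <- d[1L]; K <- d[3L]
  for (k in seq_len(K)) {
    if (max(abs(a[, , k] - t(a[, , k]))) >
        1e-8 * max(1, max(abs(a[, , k]))))
      stop("tensor slice ", k, " is not symmetric in the subject modes")
  }
  unf1 <- matrix(a, M, M * K)          # mode-1 unfolding
  s1 <- svd(unf1, nu = M, nv = 0)
  U <- fix_column_signs(s1$u)
  unf3 <- matrix(aperm(a, c(3L, 1L, 2L)), K, M * M)  # mode-3 unfolding
  s3 <- svd(unf3, nu = K, nv = 0)
  W <- fix_column_signs(s3$u)
  if (M > 1L && min(abs(diff(s1$d))) < 1e-10)
    message("hosvd: near-degenerate mode-1 singular values (gap < 1e-10)")
  core <- tmul(tmul(tmul(a, t(U), 1L), t(U), 2L), t(W), 3L)
  structure(
    list(core = core, subject_factors = U, omics_factors = W,
         mode1_sv = s1$d, mode3_sv = s3$d,
         subject_ids = dimnames(a)[[1L]] %||% as.character(seq_len(M)),
         layers = dimnames(a)[[3L]] %||% as.character(seq_len(K))),
    class = "hosvd_factors"
  )
}

## mode-n tensor-times-matrix product for 3-way arrays
tmul <- function(a, m, mode) {
  d <- dim(a)
  if (mode == 1L) {
    array(m %*% matrix(a, d[1L], d[2L] * d[3L]), c(nrow(m), d[2L], d[3L]))
  } else if (mode == 2L) {
    y <- m %*% matrix(aperm(a, c(2L, 1L, 3L)), d[2L], d[1L] * d[3L])
    aperm(array(y, c(nrow(m), d[1L], d[3L])), c(2L, 1L, 3L))
  } else {
    y <- m %*% matrix(aperm(a, c(3L, 1L, 2L)), d[3L], d[1L] * d[2L])
    aperm(array(y, c(nrow(m), d[1L], d[2L])), c(2L, 3L, 1L))
  }
}

fix_column_signs <- function(u) {
  for (j in seq_len(ncol(u))) {
    i <- which.max(abs(u[, j]))
    if (u[i, j] < 0) u[, j] <- -u[, j]
  }
  u
}

#' Reconstruct a kernel tensor from its HOSVD factors
#'
#' Evaluates the full triple-sum expansion (core contracted back with the
#' factor matrices on every mode). Up to floating-point error this
#' reproduces the decomposed tensor exactly, since the decomposition is
#' not truncated.
#'
#' @param factors an `hosvd_factors` object.
#' @return An M x M x K array.
#' @export
reconstruct_tensor <- function(factors) {
  stopifnot(inherits(factors, "hosvd_factors"))
  tmul(tmul(tmul(factors$core, factors$subject_factors, 1L),
            factors$subject_factors, 2L),
       factors$omics_factors, 3L)
}

#' Extract subject-mode factor vectors
#'
#' Returns the requested columns \eqn{u_{\ell_1 j}} of the subject-mode
#' factor matrix, with the chromosome label attached and the stabilized
#' (largest-entry-positive) sign preserved. Repeated calls on the same
#' factors return identical values.
#'
#' @param factors an `hosvd_factors` object.
#' @param l_range integer vector of factor indices \eqn{\ell_1} (1-based).
#' @param chrom optional chromosome label to attach.
#' @return An M x `length(l_range)` matrix, columns named `l<index>`, with
#'   attribute `chrom`.
#' @export
extract_subject_factors <- function(factors, l_range, chrom = NULL) {
  stopifnot(inherits(factors, "hosvd_factors"))
  M <- nrow(factors$subject_factors)
  l_range <- as.integer(l_range)
  if (length(l_range) == 0L || any(l_range < 1L) || any(l_range > M))
    stop("factor indices must lie in 1..M")
  v <- factors$subject_factors[, l_range, drop = FALSE]
  dimnames(v) <- list(factors$subject_ids, paste0("l", l_range))
  attr(v, "chrom") <- chrom
  v
}

#' @export
print.hosvd_factors <- function(x, ...) {
  cat(sprintf("hosvd_factors: %d subjects x %d layers; top mode-1 singular values: %s\n",
              nrow(x$subject_factors), nrow(x$omics_factors),
              paste(signif(utils::head(x$mode1_sv, 4), 4), collapse = ", ")))
  invisible(x)
}
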