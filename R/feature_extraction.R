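#' Project features onto a subject-mode factor
#'
#' Back-projects one subject-mode factor vector onto the features of one
#' omics layer:
#' \deqn{u_{\ell_1 i_k} = \sum_{j=1}^{M} x_{i_k j k}\, u_{\ell_1 j}}
#' Features whose subject profile tracks the factor get large-magnitude
#' scores.
#'
#' @param layer an [omics_matrix()].
#' @param subject_vector length-M numeric vector, subject order matching
#'   the layer's columns.
#' @return Numeric vector of per-feature scores, named by feature ID.
#' @export
score_features <- function(layer, subject_vector) {
  stopifnot(inherits(layer, "omics_matrix"))
  u <- as.numeric(subject_vector)
  if (length(u) != ncol(layer$values))
    stop("subject_vector length does not match the layer's subject count")
  drop(layer$values %*% u)
}

#' Chi-squared p-values for feature scores
#'
#' Under the null hypothesis that each standardized score is a zero-mean
#' Gaussian, the summed squared standardized scores over the chosen
#' factor set \eqn{\Omega} follow a chi-squared with \eqn{|\Omega|}
#' degrees of freedom; the p-value is its upper tail:
#' \deqn{P_{i_k} = P_{\chi^2}\!\left[> \sum_{\ell_1 \in \Omega}
#'   \left(\frac{u_{\ell_1 i_k}}{\sigma_{\ell_1}}\right)^2\right]}
#'
#' @param scores numeric vector (one factor) or N x \eqn{|\Omega|} matrix
#'   of per-feature scores, one column per factor in \eqn{\Omega}.
#' @param sigma positive scale \eqn{\sigma_{\ell_1}} per factor column.
#' @return Vector of raw p-values in \[0, 1\].
#' @export
#' @examples
#' chi2_pvalues(0, 1)            # 1
#' chi2_pvalues(1, 1)            # upper tail of chi^2_1 at 1
chi2_pvalues <- function(scores, sigma) {
  s <- if (is.matrix(scores)) scores else matrix(scores, ncol = 1L)
  sigma <- as.numeric(sigma)
  if (length(sigma) != ncol(s))
    stop("need one sigma per factor column")
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("sigma must be positive (degenerate scale)")
  stat <- rowSums(sweep(s, 2L, sigma, `/`)^2)
  stats::pchisq(stat, df = ncol(s), lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment (monotone, capped at
#' 1), returned in the input order.
#'
#' @param pvalues numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Score one layer against chosen factors and attach p-values
#'
#' Computes scores for every factor in the chosen set \eqn{\Omega}
#' ([score_features()]), estimates a per-factor scale
#' \eqn{\sigma_{\ell_1}} as the sample standard deviation of the scores
#' within this (layer, chromosome) family, attributes chi-squared
#' p-values ([chi2_pvalues()]), adjusts them with Benjamini-Hochberg
#' within the family, and flags features with adjusted p below `alpha`.
#'
#' Scale estimation mean-centers the scores (the null is a zero-mean
#' Gaussian); set `center = FALSE` to use the raw second moment instead.
#' Because each chromosome is decomposed independently, the BH family is
#' one (layer, chromosome); pooling across chromosomes happens afterwards
#' in [select_features()].
#'
#' @param layer an [omics_matrix()].
#' @param subject_vectors length-M vector or M x \eqn{|\Omega|} matrix of
#'   chosen subject factors for this layer's chromosome.
#' @param alpha selection threshold on adjusted p-values (default 0.01).
#' @param center center scores when estimating \eqn{\sigma_{\ell_1}}.
#' @return A data.frame of class `feature_scores` with columns
#'   `feature_id`, `chrom`, `layer`, one `score_l*` column per factor,
#'   `p`, `p_adj`, `selected`; the estimated scales are in
#'   `attr(, "sigma")`.
#' @export
feature_scores <- function(layer, subject_vectors, alpha = 0.01,
                           center = TRUE) {
  v <- if (is.matrix(subject_vectors)) subject_vectors
       else matrix(subject_vectors, ncol = 1L)
  s <- vapply(seq_len(ncol(v)), function(l) score_features(layer, v[, l]),
              numeric(nrow(layer$values)))
  s <- matrix(s, nrow = nrow(layer$values))
  sigma <- vapply(seq_len(ncol(s)), function(l) {
    x <- s[, l]
    if (center) stats::sd(x) else sqrt(sum(x^2) / max(1, length(x) - 1))
  }, numeric(1L))
  scale_floor <- pmax(apply(abs(s), 2L, max), 1) * 1e-10
  if (any(sigma <= scale_floor))
    stop("degenerate scale: all scores identical")
  p <- chi2_pvalues(s, sigma)
  p_adj <- bh_adjust(p)
  out <- data.frame(feature_id = layer$feature_ids, chrom = layer$chrom,
                    layer = layer$layer, stringsAsFactors = FALSE)
  cn <- colnames(v) %||% paste0("l", seq_len(ncol(v)))
  for (l in seq_len(ncol(s))) out[[paste0("score_", cn[l])]] <- s[, l]
  out$p <- p
  out$p_adj <- p_adj
  out$selected <- p_adj < alpha
  attr(out, "sigma") <- sigma
  class(out) <- c("feature_scores", "data.frame")
  out
}

#' Pool feature selections across chromosomes
#'
#' Combines per-(layer, chromosome) score tables, re-applies the
#' selection threshold, and returns the pooled per-layer lists of
#' selected features (as the downstream analyses pool genomic regions and
#' variants over autosomes).
#'
#' @param scores_list list of `feature_scores` data.frames (any mix of
#'   layers and chromosomes).
#' @param alpha selection threshold on adjusted p-values.
#' @return List with `table` (row-bound data.frame) and `selected` (named
#'   list per layer of selected feature IDs).
#' @export
select_features <- function(scores_list, alpha = 0.01) {
  if (inherits(scores_list, "data.frame")) scores_list <- list(scores_list)
  common <- c("feature_id", "chrom", "layer", "p", "p_adj")
  tab <- do.call(rbind, lapply(scores_list, function(d)
    as.data.frame(d)[, common]))
  tab$selected <- tab$p_adj < alpha
  sel <- lapply(split(tab, tab$layer),
                function(d) d$feature_id[d$selected])
  list(table = tab, selected = sel)
}
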