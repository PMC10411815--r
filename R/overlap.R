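#' Build a 2x2 overlap table for two feature sets in a fixed universe
#'
#' Cross-tabulates membership in two sets (e.g. transcription factors
#' identified from gene expression vs. those identified from variant
#' TFBSs) against a fixed universe — for human TFs a universe of about
#' 2000 is conventional. Layout: row 1 = not in A, row 2 = in A;
#' column 1 = not in B, column 2 = in B.
#'
#' @param setA,setB character vectors of identifiers.
#' @param universe_size total universe size (default 2000).
#' @return A 2x2 integer matrix summing to `universe_size`.
#' @export
#' @examples
#' build_overlap_table(letters[1:3], letters[2:4], 26)
build_overlap_table <- function(setA, setB, universe_size = 2000L) {
  setA <- unique(as.character(setA))
  setB <- unique(as.character(setB))
  n_union <- length(union(setA, setB))
  if (n_union > universe_size)
    stop("universe smaller than the union of the two sets")
  d <- length(intersect(setA, setB))
  b <- length(setdiff(setB, setA))
  c_ <- length(setdiff(setA, setB))
  a <- universe_size - n_union
  matrix(as.integer(c(a, b, c_, d)), 2L, 2L, byrow = TRUE,
         dimnames = list(A = c("not_selected", "selected"),
                         B = c("not_selected", "selected")))
}

#' Fisher's exact test with conditional-MLE odds ratio
#'
#' Two-sided exact test for association in a 2x2 table: the p-value sums
#' hypergeometric probabilities (all margins fixed) of every table no
#' more probable than the observed one, and the odds ratio is the
#' conditional maximum-likelihood estimate under the noncentral
#' hypergeometric model — the estimator conventionally reported next to
#' the exact test (it differs from the sample cross-product ratio).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return List with `odds_ratio` (conditional MLE; 0 or `Inf` when a
#'   margin cell forces it, with `boundary = TRUE`) and `pvalue`.
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(10, 10, 10, 10), 2, 2))  # OR 1, p 1
fisher_exact_2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table")
  if (anyNA(tab) || any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  ft <- stats::fisher.test(tab)
  or <- unname(ft$estimate)
  list(odds_ratio = or, pvalue = ft$p.value,
       boundary = !is.finite(or) || or == 0)
}

#' Example TF-overlap contingency tables
#'
#' Five 2x2 tables comparing transcription factors identified from gene
#' expression with those identified from the transcription-factor binding
#' sites of selected genomic variants, in three immune cell types (CD4 T
#' cells, neutrophils, monocytes) under two factor-selection sets, within
#' a universe of 2000 human TFs. Shipped as a plain-text fixture for the
#' overlap-validation stage.
#'
#' @return data.frame with columns `cell_type`, `factor_set`, `neither`,
#'   `expr_only`, `tfbs_only`, `both`, `universe`.
#' @export
tf_overlap_tables <- function() {
  path <- system.file("extdata", "tf_overlap_counts.tsv", package = "ktdfe",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Run Fisher's exact test on each shipped TF-overlap table
#'
#' @param tables data.frame in the layout of [tf_overlap_tables()].
#' @return The input with `odds_ratio` and `pvalue` columns appended.
#' @export
tf_overlap_fisher <- function(tables = tf_overlap_tables()) {
  res <- lapply(seq_len(nrow(tables)), function(i) {
    tab <- matrix(c(tables$neither[i], tables$expr_only[i],
                    tables$tfbs_only[i], tables$both[i]),
                  2L, 2L, byrow = TRUE)
    stopifnot(sum(tab) == tables$universe[i])
    fisher_exact_2x2(tab)
  })
  tables$odds_ratio <- vapply(res, `[[`, numeric(1L), "odds_ratio")
  tables$pvalue <- vapply(res, `[[`, numeric(1L), "pvalue")
  tables
}
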