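#' Average absolute cross-chromosome correlation of subject vectors
#'
#' For a target chromosome, the mean over all other chromosomes of the
#' absolute Pearson correlation between the target's subject vector and
#' each other chromosome's vector:
#' \deqn{\langle\rho_{chr}\rangle = \frac{1}{C-1} \sum_{chr' \neq chr}
#'   |\rho(u^{chr}, u^{chr'})|}
#' A subject pattern that recurs across chromosomes is unlikely to be
#' chance, which is what makes this the selection criterion in a cohort
#' with no case/control labels.
#'
#' @param vectors M x C matrix of subject vectors, one column per
#'   chromosome (column names = chromosome labels), or a named list of
#'   length-M vectors.
#' @param target_chrom chromosome label or column index of the target.
#' @return The scalar \eqn{\langle\rho_{chr}\rangle \in [0, 1]}.
#' @export
average_cross_chromosome_correlation <- function(vectors, target_chrom) {
  v <- as_vector_matrix(vectors)
  if (ncol(v) < 2L) stop("need vectors from at least two chromosomes")
  if (is.character(target_chrom)) {
    target <- match(target_chrom, colnames(v))
    if (is.na(target)) stop("unknown chromosome: ", target_chrom)
  } else target <- as.integer(target_chrom)
  sds <- apply(v, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance subject vector: correlation undefined")
  r <- abs(stats::cor(v[, target], v[, -target, drop = FALSE]))
  mean(r)
}

as_vector_matrix <- function(vectors) {
  if (is.list(vectors)) {
    v <- do.call(cbind, vectors)
    if (!is.null(names(vectors))) colnames(v) <- names(vectors)
    v
  } else as.matrix(vectors)
}

#' Choose the cross-chromosome "max correlated" factor set
#'
#' Assigns to every chromosome one subject-mode factor index \eqn{\ell_1}
#' (from `candidates`) so that the chosen subject vectors are maximally
#' correlated across chromosomes. The assignment is found by coordinate
#' ascent: each chromosome is initialized to the candidate with the
#' largest total absolute correlation against all candidates of all other
#' chromosomes, then chromosomes are updated one at a time to maximize
#' \eqn{\langle\rho_{chr}\rangle} against the current assignment until a
#' fixed point is reached (the symmetric objective is non-decreasing at
#' every update, so this terminates). Ties go to the smaller \eqn{\ell_1}.
#'
#' The default candidate range starts at 2 because with raw non-negative
#' omics values the first factor captures the overall signal mean, which
#' is trivially shared across chromosomes.
#'
#' @param factors_by_chrom named list (one element per chromosome) of
#'   `hosvd_factors` objects, or of M x M subject-factor matrices.
#' @param candidates integer vector of candidate \eqn{\ell_1} indices.
#' @param max_iter safety cap on coordinate-ascent sweeps.
#' @return An object of class `factor_selection`: list with `set`
#'   (`"max_correlated"`), `chosen` (named integer vector of \eqn{\ell_1}
#'   per chromosome), `vectors` (M x C matrix of the chosen subject
#'   vectors, signs aligned to the first chromosome by positive
#'   correlation), `rho_chr` (per-chromosome \eqn{\langle\rho_{chr}\rangle}),
#'   and `candidates`.
#' @export
choose_max_correlated_factors <- function(factors_by_chrom,
                                          candidates = 2:5,
                                          max_iter = 100L) {
  candidates <- sort(unique(as.integer(candidates)))  # tie-break: smaller l1
  if (length(candidates) == 0L) stop("empty candidate range")
  mats <- lapply(factors_by_chrom, function(f)
    if (inherits(f, "hosvd_factors")) f$subject_factors else as.matrix(f))
  C <- length(mats)
  if (C < 2L) stop("need at least two chromosomes")
  chroms <- names(mats) %||% paste0("chr", seq_len(C))
  M <- nrow(mats[[1L]])
  if (any(candidates < 1L) || any(candidates > M))
    stop("candidate indices must lie in 1..M")
  L <- length(candidates)
  ## absolute correlations between every candidate column of every
  ## chromosome pair
  cand <- lapply(mats, function(m) m[, candidates, drop = FALSE])
  R <- array(NA_real_, c(C, C, L, L))
  for (a in seq_len(C - 1L)) for (b in (a + 1L):C) {
    r <- abs(stats::cor(cand[[a]], cand[[b]]))
    R[a, b, , ] <- r
    R[b, a, , ] <- t(r)
  }
  ## coordinate ascent is local, so run it from several deterministic
  ## starts and keep the best objective: (a) each chromosome set to the
  ## candidate with the largest total |rho| against all other
  ## chromosomes' candidates, (b) one uniform start per candidate. A
  ## uniform start is needed because a factor whose eigenvector splits
  ## across two candidate columns of some chromosome collects several
  ## medium correlations and can beat a clean factor's single large one
  ## under start (a).
  objective <- function(assign) {
    tot <- 0
    for (a in seq_len(C - 1L)) for (b in (a + 1L):C)
      tot <- tot + matrix(R[a, b, , ], L, L)[assign[a], assign[b]]
    tot
  }
  ascend <- function(assign) {
    for (it in seq_len(max_iter)) {
      changed <- FALSE
      for (a in seq_len(C)) {
        sc <- numeric(L)
        for (b in setdiff(seq_len(C), a))
          sc <- sc + matrix(R[a, b, , ], L, L)[, assign[b]]
        best <- which.max(sc)  # first max = smallest candidate on ties
        if (sc[best] > sc[assign[a]] + 1e-12 && best != assign[a]) {
          assign[a] <- best
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    assign
  }
  init_total <- integer(C)
  for (a in seq_len(C)) {
    tot <- numeric(L)
    for (b in setdiff(seq_len(C), a))
      tot <- tot + rowSums(matrix(R[a, b, , ], L, L))
    init_total[a] <- which.max(tot)
  }
  starts <- c(list(init_total),
              lapply(seq_len(L), function(l) rep(l, C)))
  fits <- lapply(starts, ascend)
  objs <- vapply(fits, objective, numeric(1L))
  ## among (near-)tied optima prefer the lexicographically smallest
  ## assignment, i.e. the smaller l1
  near <- which(objs >= max(objs) - 1e-12)
  keys <- vapply(fits[near], function(f) paste(sprintf("%04d", f),
                                               collapse = ","), character(1L))
  assign <- fits[near][[order(keys)[1L]]]
  chosen <- candidates[assign]
  names(chosen) <- chroms
  vectors <- sapply(seq_len(C), function(a) cand[[a]][, assign[a]])
  colnames(vectors) <- chroms
  rownames(vectors) <- rownames(mats[[1L]])
  ## align signs to the first chromosome (Eq. 5 is sign-invariant; this
  ## just makes the output deterministic and plottable)
  for (a in seq_len(C)[-1L]) {
    if (stats::cor(vectors[, 1L], vectors[, a]) < 0)
      vectors[, a] <- -vectors[, a]
  }
  rho_chr <- vapply(seq_len(C), function(a)
    average_cross_chromosome_correlation(vectors, a), numeric(1L))
  names(rho_chr) <- chroms
  structure(list(set = "max_correlated", chosen = chosen,
                 vectors = vectors, rho_chr = rho_chr,
                 candidates = candidates),
            class = "factor_selection")
}

#' @export
print.factor_selection <- function(x, ...) {
  cat(sprintf("factor_selection (%s): l1 = {%s}; mean <rho_chr> = %.3f\n",
              x$set, paste(x$chosen, collapse = ","), mean(x$rho_chr)))
  invisible(x)
}

## two-sided Pearson correlation test p-value via the t transform
## (identical to cor.test's pearson path), vectorized over r
cor_test_p <- function(r, n) {
  if (n < 4L) stop("need at least 4 subjects for a correlation test")
  r <- pmin(pmax(r, -1), 1)
  stat <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(stat, df = n - 2, lower.tail = FALSE)
}

#' Count significantly correlated chromosome pairs
#'
#' Tests every pair of chromosomes' chosen subject vectors for nonzero
#' Pearson correlation (two-sided t test), adjusts the \eqn{C(C-1)/2}
#' p-values with Benjamini-Hochberg, and counts pairs below/at-or-above
#' each threshold.
#'
#' @param vectors M x C matrix (or named list) of subject vectors.
#' @param thresholds significance thresholds on the adjusted p-values.
#' @return List with `pairs` (data.frame: chrom_a, chrom_b, rho, p,
#'   p_adj) and `counts` (data.frame: threshold, below, at_or_above).
#' @export
count_significant_pairs <- function(vectors, thresholds = c(0.01, 0.05)) {
  v <- as_vector_matrix(vectors)
  C <- ncol(v)
  if (C < 2L) stop("need at least two chromosomes")
  M <- nrow(v)
  if (M < 4L) stop("need at least 4 subjects for a correlation test")
  chroms <- colnames(v) %||% paste0("chr", seq_len(C))
  idx <- which(upper.tri(matrix(0, C, C)), arr.ind = TRUE)
  rho <- stats::cor(v)[idx]
  p <- cor_test_p(rho, M)
  p_adj <- stats::p.adjust(p, method = "BH")
  pairs <- data.frame(chrom_a = chroms[idx[, 1L]],
                      chrom_b = chroms[idx[, 2L]],
                      rho = rho, p = p, p_adj = p_adj)
  counts <- data.frame(
    threshold = thresholds,
    below = vapply(thresholds, function(t) sum(p_adj < t), integer(1L)),
    at_or_above = vapply(thresholds, function(t) sum(p_adj >= t), integer(1L))
  )
  list(pairs = pairs, counts = counts)
}

#' Screen candidate factors against clinical covariates
#'
#' Correlates every candidate subject-mode factor vector of a reference
#' chromosome with every clinical variable (Pearson, two-sided t test),
#' adjusts all (variable x candidate) p-values with Benjamini-Hochberg,
#' and flags a candidate as clinically correlated when at least one
#' variable reaches adjusted p below `alpha`. Datasets where no candidate
#' is flagged have no clinically correlated set.
#'
#' @param subject_factors M x M subject-factor matrix (or `hosvd_factors`)
#'   of the reference chromosome — by convention the chromosome with the
#'   highest \eqn{\langle\rho_{chr}\rangle}.
#' @param clinical data.frame or matrix of clinical variables, subjects in
#'   rows (aligned with the factor rows), variables in columns. Constant
#'   variables are skipped with a warning.
#' @param candidates candidate \eqn{\ell_1} indices.
#' @param alpha flag threshold on adjusted p-values (default 0.05).
#' @return List with `table` (data.frame: variable, l1, rho, p, p_adj,
#'   flagged) and `flagged_l1` (integer vector of clinically correlated
#'   candidates, possibly empty).
#' @export
clinical_correlation_screen <- function(subject_factors, clinical,
                                        candidates = 2:5, alpha = 0.05) {
  if (inherits(subject_factors, "hosvd_factors"))
    subject_factors <- subject_factors$subject_factors
  u <- as.matrix(subject_factors)
  candidates <- as.integer(candidates)
  if (length(candidates) == 0L) stop("empty candidate range")
  cl <- as.data.frame(clinical)
  cl <- cl[vapply(cl, is.numeric, logical(1L))]
  if (nrow(cl) != nrow(u))
    stop("clinical table and subject factors describe different subjects")
  const <- vapply(cl, function(x) stats::sd(x, na.rm = TRUE) == 0, logical(1L))
  if (any(const)) {
    warning("skipping constant clinical variable(s): ",
            paste(names(cl)[const], collapse = ", "))
    cl <- cl[!const]
  }
  if (ncol(cl) == 0L) stop("no usable clinical variables")
  uc <- u[, candidates, drop = FALSE]
  rho <- stats::cor(as.matrix(cl), uc)      # variables x candidates
  p <- cor_test_p(as.vector(rho), nrow(u))
  p_adj <- stats::p.adjust(p, method = "BH")
  tab <- data.frame(
    variable = rep(colnames(cl) %||% paste0("v", seq_len(ncol(cl))),
                   times = length(candidates)),
    l1 = rep(candidates, each = ncol(cl)),
    rho = as.vector(rho), p = p, p_adj = p_adj
  )
  tab$flagged <- tab$p_adj < alpha
  flagged_l1 <- sort(unique(tab$l1[tab$flagged]))
  list(table = tab, flagged_l1 = flagged_l1)
}
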