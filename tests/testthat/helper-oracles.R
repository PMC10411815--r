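## Independent brute-force oracles. These deliberately share no code with
## the implementation: per-base loops, double/triple summation, textbook
## definitions.

## per-base accumulation: walk every nucleotide of every interval
oracle_bin_per_base <- function(d, bin_size, n_bins, mode) {
  acc <- numeric(n_bins)   # value mass per bin
  cov <- numeric(n_bins)   # covered base count per bin
  for (i in seq_len(nrow(d))) {
    len <- d$end[i] - d$start[i]
    for (pos in seq(d$start[i], d$end[i] - 1)) {
      b <- pos %/% bin_size + 1
      acc[b] <- acc[b] + d$value[i] / len
      cov[b] <- cov[b] + 1
    }
  }
  if (mode == "sum") return(acc)
  out <- numeric(n_bins)
  for (i in seq_len(nrow(d))) {
    for (pos in seq(d$start[i], d$end[i] - 1)) {
      b <- pos %/% bin_size + 1
      out[b] <- out[b] + d$value[i]
    }
  }
  ifelse(cov > 0, out / cov, 0)
}

## count non-reference alleles call by call
oracle_dose <- function(gt) {
  parts <- strsplit(gt, "[/|]")
  vapply(parts, function(a) {
    if (any(a == ".")) return(NA_real_)
    sum(as.numeric(a) > 0)
  }, numeric(1))
}

## Eq. 1 by explicit double loop over subject pairs
oracle_kernel <- function(layers) {
  M <- ncol(layers[[1]]$values)
  K <- length(layers)
  out <- array(NA_real_, c(M, M, K))
  for (k in seq_len(K)) {
    X <- layers[[k]]$values
    for (j in seq_len(M)) for (jp in seq_len(M))
      out[j, jp, k] <- sum(X[, j] * X[, jp])
  }
  out
}

## Eq. 2 by explicit triple summation
oracle_reconstruct <- function(hf) {
  G <- hf$core; U <- hf$subject_factors; W <- hf$omics_factors
  M <- nrow(U); K <- nrow(W)
  out <- array(0, c(M, M, K))
  for (j in seq_len(M)) for (jp in seq_len(M)) for (k in seq_len(K)) {
    s <- 0
    for (l1 in seq_len(M)) for (l2 in seq_len(M)) for (l3 in seq_len(K))
      s <- s + G[l1, l2, l3] * U[j, l1] * U[jp, l2] * W[k, l3]
    out[j, jp, k] <- s
  }
  out
}

## Benjamini-Hochberg step-up from the definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  sorted <- p[o] * n / seq_len(n)
  ## monotone: min over j >= i
  for (i in seq_len(n)) adj[i] <- min(sorted[i:n], 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

## two-sided Fisher exact p by full enumeration of the hypergeometric
## support (fixed margins), probability-mass rule
oracle_fisher_p <- function(tab) {
  m <- tab[1, 1] + tab[2, 1]   # col-1 margin
  n <- tab[1, 2] + tab[2, 2]
  k <- tab[1, 1] + tab[1, 2]   # row-1 margin
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

rand_sym_tensor <- function(M, K) {
  a <- array(0, c(M, M, K))
  for (k in seq_len(K)) {
    s <- matrix(rnorm(M * M), M, M)
    a[, , k] <- (s + t(s)) / 2
  }
  a
}

## compact simulated cohort for smoke/determinism tests
small_config <- function(seed, ...) {
  simulation_config(M = 60L, C = 3L,
                    n_features = c(expression = 300L, methylation = 300L,
                                   variant = 1500L),
                    seed = seed, ...)
}

rand_omics <- function(N, M, layer = "expression", chrom = "chr1") {
  omics_matrix(matrix(rnorm(N * M), N, M), layer = layer, chrom = chrom)
}
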