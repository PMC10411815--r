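test_that("the cross-chromosome correlation average hits its limits", {
  set.seed(51)
  v <- rnorm(30)
  same <- cbind(chr1 = v, chr2 = 2 * v + 1, chr3 = -v)
  expect_equal(average_cross_chromosome_correlation(same, "chr1"), 1)

  ## exactly decorrelated other vectors
  a <- rnorm(30); b <- rnorm(30)
  b <- b - mean(b); a <- a - mean(a)
  b_orth <- b - sum(a * b) / sum(a * a) * a
  expect_equal(average_cross_chromosome_correlation(
    cbind(a, b_orth, b_orth), 1), 0, tolerance = 1e-12)

  ## three chromosomes against the hand formula
  m <- matrix(rnorm(90), 30, 3)
  want <- (abs(cor(m[, 1], m[, 2])) + abs(cor(m[, 1], m[, 3]))) / 2
  expect_equal(average_cross_chromosome_correlation(m, 1), want)

  ## sign-flip invariance
  m2 <- m; m2[, 2] <- -m2[, 2]
  expect_equal(average_cross_chromosome_correlation(m2, 1),
               average_cross_chromosome_correlation(m, 1))

  expect_error(average_cross_chromosome_correlation(
    cbind(rep(1, 30), rnorm(30)), 1), "zero-variance")
})

test_that("identical factor matrices choose the same index with rho 1", {
  set.seed(52)
  U <- qr.Q(qr(matrix(rnorm(64), 8, 8)))
  sel <- choose_max_correlated_factors(list(chr1 = U, chr2 = U),
                                       candidates = 2:4)
  expect_equal(unname(sel$chosen), c(2L, 2L))  # tie broken to smaller l1
  expect_equal(unname(sel$rho_chr), c(1, 1), tolerance = 1e-12)
})

test_that("the chosen assignment beats every uniform assignment", {
  set.seed(53)
  mats <- replicate(4, matrix(rnorm(20 * 6), 20, 6), simplify = FALSE)
  names(mats) <- paste0("chr", 1:4)
  sel <- choose_max_correlated_factors(mats, candidates = 2:5)
  obj <- function(vectors) mean(vapply(seq_len(ncol(vectors)), function(a)
    average_cross_chromosome_correlation(vectors, a), numeric(1)))
  got <- obj(sel$vectors)
  for (l in 2:5) {
    uni <- sapply(mats, function(m) m[, l])
    expect_gte(got, obj(uni) - 1e-9)
  }
  expect_error(choose_max_correlated_factors(mats, integer(0)), "empty")
})

test_that("factor selection recovers a planted shared factor", {
  run <- run_pipeline(simulation_config(seed = 97))
  truth <- run$sim$truth
  cors <- apply(run$selection$vectors, 2,
                function(v) abs(cor(v, truth$f_shared)))
  expect_true(all(cors > 0.9))
  expect_true(all(run$selection$rho_chr > 0.9))
})

test_that("pair counting behaves at the limits and under BH", {
  set.seed(54)
  v <- rnorm(50)
  same22 <- matrix(v, 50, 22)
  r <- count_significant_pairs(same22 +
                                 matrix(rnorm(50 * 22, sd = 1e-6), 50, 22))
  expect_equal(nrow(r$pairs), 231L)
  expect_equal(r$counts$below, c(231L, 231L))

  two <- count_significant_pairs(matrix(rnorm(100), 50, 2))
  expect_equal(nrow(two$pairs), 1L)

  many <- count_significant_pairs(matrix(rnorm(50 * 8), 50, 8))
  expect_true(all(many$pairs$p_adj >= many$pairs$p))
  below <- many$counts$below[match(c(0.01, 0.05), many$counts$threshold)]
  expect_gte(below[2], below[1])
  expect_equal(many$counts$below + many$counts$at_or_above,
               rep(28L, 2))

  expect_error(count_significant_pairs(matrix(rnorm(6), 3, 2)),
               "at least 4 subjects")
})

test_that("pair p-values match cor.test and hold the nominal null rate", {
  set.seed(55)
  m <- matrix(rnorm(40 * 3), 40, 3)
  r <- count_significant_pairs(m)
  ct <- cor.test(m[, 1], m[, 2])
  expect_equal(r$pairs$p[1], ct$p.value, tolerance = 1e-12)

  ## 200 replicates of independent vectors: raw p < 0.05 in ~5% of pairs
  hits <- 0L; total <- 0L
  for (rep in 1:200) {
    v <- matrix(rnorm(100 * 10), 100, 10)
    pr <- count_significant_pairs(v)$pairs
    hits <- hits + sum(pr$p < 0.05)
    total <- total + nrow(pr)
  }
  expect_lt(abs(hits / total - 0.05), 0.01)
})

test_that("the clinical screen flags real associations and not noise", {
  set.seed(56)
  U <- qr.Q(qr(matrix(rnorm(100 * 100), 100, 100)))
  clin <- data.frame(x = U[, 3], y = rnorm(100))
  r <- clinical_correlation_screen(U, clin, candidates = 2:5)
  row <- r$table[r$table$variable == "x" & r$table$l1 == 3, ]
  expect_equal(abs(row$rho), 1, tolerance = 1e-10)
  expect_true(row$flagged)
  expect_true(3 %in% r$flagged_l1)

  ## constant variable is skipped, not fatal
  expect_warning(
    r2 <- clinical_correlation_screen(U, data.frame(c0 = rep(1, 100),
                                                    y = rnorm(100)),
                                      candidates = 2:3),
    "constant")
  expect_false(any(r2$table$variable == "c0"))

  ## null: independent clinical variables are rarely flagged
  flags <- 0L
  for (rep in 1:200) {
    Un <- qr.Q(qr(matrix(rnorm(100 * 6), 100, 6)))
    cl <- as.data.frame(matrix(rnorm(100 * 7), 100, 7))
    rn <- clinical_correlation_screen(Un, cl, candidates = 2:5)
    if (length(rn$flagged_l1)) flags <- flags + 1L
  }
  expect_lt(flags / 200, 0.10)  # nominal family-wise rate 0.05 + MC slack
})

test_that("a planted clinical factor is flagged through the screen", {
  run <- run_pipeline(simulation_config(seed = 98))
  truth <- run$sim$truth
  U <- run$factors[[run$manifest$reference_chrom]]$subject_factors
  best <- (2:5)[which.max(abs(cor(U[, 2:5], truth$f_clinical)))]
  expect_true(best %in% run$clinical_screen$flagged_l1)
})
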