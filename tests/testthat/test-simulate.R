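test_that("the generator is deterministic under a fixed seed", {
  cfg <- small_config(3)
  a <- simulate_multiomics(cfg)
  b <- simulate_multiomics(cfg)
  expect_identical(a$layers, b$layers)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth$f_shared, b$truth$f_shared)
  c_ <- simulate_multiomics(small_config(4))
  expect_false(identical(a$layers$chr1$expression$values,
                         c_$layers$chr1$expression$values))
})

test_that("with no noise a planted row is an exact multiple of the factor", {
  cfg <- simulation_config(M = 20L, C = 1L,
                           n_features = c(expression = 10L,
                                          methylation = 10L, variant = 5L),
                           baseline = c(expression = 0, methylation = 50),
                           noise_sd = c(expression = 0, methylation = 0),
                           frac_shared = c(expression = 0.1,
                                           methylation = 0.1, variant = 0.2),
                           frac_clinical = c(expression = 0,
                                             methylation = 0, variant = 0),
                           clip = FALSE, seed = 8)
  sim <- simulate_multiomics(cfg)
  pl <- sim$truth$planted$chr1$expression
  id <- pl$shared[1]
  a <- pl$loading_shared[[id]]
  expect_equal(unname(sim$layers$chr1$expression$values[id, ]),
               a * sim$truth$f_shared)
  ## background rows are exactly baseline
  bg <- setdiff(sim$layers$chr1$expression$feature_ids, pl$shared)
  expect_true(all(sim$layers$chr1$expression$values[bg, ] == 0))
})

test_that("genotype dosages are integers in 0..2 and clinical links are real", {
  sim <- simulate_multiomics(small_config(9))
  for (chrom in names(sim$layers)) {
    v <- sim$layers[[chrom]]$variant$values
    expect_true(all(v %in% c(0, 1, 2)))
  }
  ## linked clinical variables correlate with the clinical factor
  for (nm in sim$truth$clinical_linked)
    expect_gt(abs(cor(sim$clinical[[nm]], sim$truth$f_clinical)), 0.3)
  ## methylation stays within percentage bounds
  expect_true(all(sim$layers$chr1$methylation$values >= 0 &
                    sim$layers$chr1$methylation$values <= 100))
})

test_that("infeasible clipping warns", {
  cfg <- simulation_config(M = 10L, C = 1L,
                           n_features = c(expression = 50L,
                                          methylation = 50L, variant = 5L),
                           baseline = c(expression = 1, methylation = 50),
                           loading_shared = c(expression = 50,
                                              methylation = 0.1,
                                              variant = 0.1),
                           frac_shared = c(expression = 0.9,
                                           methylation = 0.02,
                                           variant = 0.2),
                           seed = 2)
  expect_warning(simulate_multiomics(cfg), "clipping")
})

test_that("recovery metrics follow the set-arithmetic definitions", {
  sim <- simulate_multiomics(small_config(10))
  planted <- lapply(
    stats::setNames(nm = c("expression", "methylation", "variant")),
    function(lay) unique(unlist(lapply(sim$truth$planted, function(ch)
      ch[[lay]]$shared))))

  perfect <- recovery_metrics(planted, sim$truth)
  expect_true(all(perfect$precision == 1))
  expect_true(all(perfect$recall == 1))

  none <- recovery_metrics(list(expression = character()), sim$truth)
  pooled <- none[none$layer == "pooled", ]
  expect_equal(pooled$recall, 0)
  expect_true(is.na(pooled$precision))

  set.seed(73)
  some <- lapply(planted, function(x) sample(x, length(x) %/% 2))
  mixed <- c(some["expression"],
             list(methylation = c(some$methylation, "not_a_feature")))
  r <- recovery_metrics(mixed, sim$truth)
  me <- r[r$layer == "methylation", ]
  expect_equal(me$tp, length(some$methylation))
  expect_equal(me$precision,
               length(some$methylation) / (length(some$methylation) + 1))
  expect_equal(me$recall,
               length(some$methylation) / length(planted$methylation))
})

test_that("recall grows with the planted loading strength", {
  grid <- list(c(expression = 4, methylation = 2, variant = 0.3),
               c(expression = 10, methylation = 5, variant = 0.8),
               c(expression = 30, methylation = 12, variant = 1.5))
  mean_recall <- vapply(grid, function(ls) {
    rs <- vapply(1:20, function(s) {
      run <- run_pipeline(small_config(200 + s, loading_shared = ls))
      run$metrics[run$metrics$layer == "pooled", "recall"]
    }, numeric(1))
    mean(rs)
  }, numeric(1))
  expect_true(all(diff(mean_recall) > -0.02))
  expect_gt(mean_recall[3], mean_recall[1])
})
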