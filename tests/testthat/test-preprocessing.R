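test_that("an interval inside one region lands there and empty input follows the length policy", {
  iv <- data.frame(chrom = "chr1", start = 100, end = 200, value = 4)
  v <- bin_signal(iv, bin_size = 25000, chrom_length = 100000)
  expect_equal(nrow(v), 4L)
  expect_equal(v[, 1], c(4, 0, 0, 0))

  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), value = numeric())
  expect_equal(nrow(bin_signal(empty, bin_size = 25000)), 0L)
  withlen <- bin_signal(empty, bin_size = 25000, chrom_length = 50000)
  expect_equal(withlen[, 1], c(0, 0))
})

test_that("binning matches a per-base accumulation oracle and conserves mass", {
  set.seed(11)
  bs <- 100
  for (mode in c("sum", "mean")) {
    start <- sample(0:360, 50)
    len <- sample(1:120, 50, replace = TRUE)  # intervals span up to 2+ bins
    d <- data.frame(chrom = "chr1", start = start, end = start + len,
                    value = round(runif(50, 0, 10), 3))
    got <- bin_signal(d, bin_size = bs, mode = mode,
                      chrom_length = 500)[, 1]
    want <- oracle_bin_per_base(d, bs, 5L, mode)
    expect_equal(got, want, tolerance = 1e-12)
    if (mode == "sum")
      expect_equal(sum(got), sum(d$value), tolerance = 1e-9)
    ## invariant to interval order
    perm <- sample(nrow(d))
    expect_equal(bin_signal(d[perm, ], bin_size = bs, mode = mode,
                            chrom_length = 500)[, 1], got)
  }
})

test_that("binning rejects bad coordinates and mixed chromosomes", {
  expect_error(bin_signal(data.frame(chrom = "chr1", start = -5, end = 10,
                                     value = 1)), "negative")
  expect_error(bin_signal(data.frame(chrom = "chr1", start = 10, end = 10,
                                     value = 1)), "start < end")
  expect_error(bin_signal(data.frame(chrom = c("chr1", "chr2"),
                                     start = c(0, 0), end = c(5, 5),
                                     value = 1)), "mixed chromosomes")
})

test_that("multi-subject binning builds an omics_matrix with region ids", {
  ivs <- list(
    A = data.frame(chrom = "chr1", start = 0, end = 30000, value = 3),
    B = data.frame(chrom = "chr1", start = 25000, end = 50000, value = 6))
  om <- bin_signal(ivs, bin_size = 25000, mode = "sum")
  expect_s3_class(om, "omics_matrix")
  expect_equal(om$subject_ids, c("A", "B"))
  expect_equal(om$feature_ids, c("chr1:0-25000", "chr1:25000-50000"))
  ## 5/6 of subject A's interval covers region 1
  expect_equal(om$values[, "A"], c(3 * 25/30, 3 * 5/30),
               ignore_attr = TRUE)
  expect_equal(om$values[, "B"], c(0, 6), ignore_attr = TRUE)
})

test_that("genotype encoding counts non-reference alleles and imputes missing", {
  g <- matrix(c("0/0", "0/1", "1/1"), 1, 3,
              dimnames = list("v1", c("a", "b", "c")))
  expect_equal(encode_genotypes(g)$values["v1", ], c(a = 0, b = 1, c = 2))

  gm <- matrix(c("0/1", "./.", "0|1"), 1, 3)
  expect_equal(unname(encode_genotypes(gm)$values[1, ]), c(1, 1, 1))

  ## drop-variant policy removes the row with missingness
  g2 <- rbind(gm, matrix(c("0/0", "1/1", "0/0"), 1, 3))
  expect_equal(nrow(encode_genotypes(g2, missing = "drop")$values), 1L)

  allmiss <- rbind(matrix("./.", 1, 3), matrix("0/1", 1, 3))
  expect_warning(om <- encode_genotypes(allmiss), "missing in all subjects")
  expect_equal(nrow(om$values), 1L)

  expect_error(encode_genotypes(matrix(c("0", "1", "0"), 1, 3)), "ploidy")
  expect_error(encode_genotypes(matrix(c("0/1/1", "0/0", "0/0"), 1, 3)),
               "ploidy")
})

test_that("random genotype matrices match the allele-count oracle", {
  set.seed(21)
  gts <- c("0/0", "0/1", "1/0", "1/1", "0|1", "1|1", "0/2", "2/2", "./.")
  g <- matrix(sample(gts, 100 * 20, replace = TRUE), 100, 20)
  om <- encode_genotypes(g, missing = "mean")
  want <- matrix(oracle_dose(as.vector(g)), 100, 20)
  keep <- rowSums(!is.na(want)) > 0
  want <- want[keep, , drop = FALSE]
  for (i in seq_len(nrow(want)))
    want[i, is.na(want[i, ])] <- mean(want[i, ], na.rm = TRUE)
  expect_equal(unname(om$values), want)
  expect_true(all(om$values >= 0 & om$values <= 2))
  ## integer-valued wherever the row had no missing call
  intact <- rowSums(is.na(matrix(oracle_dose(as.vector(g)), 100, 20)[keep, ])) == 0
  expect_true(all(om$values[intact, ] == round(om$values[intact, ])))
})

test_that("a simulated cohort round-trips through the on-disk formats", {
  cfg <- simulation_config(M = 5L, C = 1L,
                           n_features = c(expression = 8L, methylation = 8L,
                                          variant = 12L),
                           seed = 5)
  sim <- simulate_multiomics(cfg)
  dir <- withr::local_tempdir()
  write_sim_dataset(sim, dir)

  beds <- list.files(file.path(dir, "methylation", "chr1"),
                     full.names = TRUE)
  names(beds) <- sub("\\.bed$", "", basename(beds))
  om <- read_bed_signal(beds[sim$layers$chr1$methylation$subject_ids],
                        bin_size = cfg$bin_size, mode = "mean",
                        layer = "methylation")
  expect_equal(om$values, sim$layers$chr1$methylation$values,
               tolerance = 1e-9, ignore_attr = TRUE)

  vom <- read_012_tsv(file.path(dir, "variant", "chr1.tsv"), chrom = "chr1")
  expect_equal(vom$values, sim$layers$chr1$variant$values,
               ignore_attr = TRUE)
})

test_that("VCF genotypes decode through the vcfR route", {
  skip_if_not_installed("vcfR")
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tA\tB\tC",
    "chr1\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\tv2\tC\tT\t.\tPASS\t.\tGT\t0|1\t./.\t1|1")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  out <- read_vcf_genotypes(path)
  expect_named(out, "chr1")
  expect_equal(unname(out$chr1$values[1, ]), c(0, 1, 2))
  expect_equal(unname(out$chr1$values[2, ]), c(1, 1.5, 2))  # mean-imputed
})
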