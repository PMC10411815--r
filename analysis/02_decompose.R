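#!/usr/bin/env Rscript
## Build the per-chromosome subject-pair kernel tensors (Eq. x_jj'k =
## sum_i x_ij x_ij' per layer) and decompose each by HOSVD. The leading
## mode-1 singular value captures the overall signal mean; the planted
## factors appear next, well separated from the noise floor.
library(ktdfe)

seed <- as.integer(Sys.getenv("KTDFE_SEED", "1"))
dir.create("results", showWarnings = FALSE)

sim <- simulate_multiomics(simulation_config(seed = seed))
factors <- lapply(sim$layers, function(lys) hosvd(build_kernel_tensor(lys)))

sv <- do.call(rbind, lapply(names(factors), function(chrom)
  data.frame(chrom = chrom, l1 = 1:6,
             mode1_sv = signif(factors[[chrom]]$mode1_sv[1:6], 4))))
write.table(sv, "results/singular_values.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

gap <- vapply(factors, function(f) f$mode1_sv[4] / f$mode1_sv[5], numeric(1))
message(sprintf(
  "decomposed %d chromosomes; factor-to-noise singular value ratio (l1=4 vs 5): %s",
  length(factors), paste(round(gap, 1), collapse = ", ")))
message("wrote results/singular_values.tsv")
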