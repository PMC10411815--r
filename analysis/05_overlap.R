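#!/usr/bin/env Rscript
## Validate overlap between TF sets with Fisher's exact test: the shipped
## 2x2 tables compare TFs targeting genes in selected genomic regions
## (from expression) with TFs whose binding sites contain selected
## genomic variants, in a universe of ~2000 human TFs.
library(ktdfe)

dir.create("results", showWarnings = FALSE)

res <- tf_overlap_fisher()
res$odds_ratio <- signif(res$odds_ratio, 7)
res$pvalue <- signif(res$pvalue, 4)
write.table(res, "results/tf_overlap_fisher.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

for (i in seq_len(nrow(res)))
  message(sprintf("%-12s %-22s OR = %.6f, P = %.5f",
                  res$cell_type[i], res$factor_set[i],
                  res$odds_ratio[i], res$pvalue[i]))
message("wrote results/tf_overlap_fisher.tsv")
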