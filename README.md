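# ktdfe — kernel tensor decomposition-based unsupervised feature extraction for multiomics

`ktdfe` integrates gene expression, DNA methylation and genomic variants
measured on the **same subjects** — the setting of population cohorts of
healthy individuals, where there are no case/control labels and hence no
differential signal to test. Instead of comparing groups, the package
finds subject-level patterns that recur across chromosomes and across
omics layers, then selects the genomic regions and variants that carry
those patterns.

It is aimed at analysts of cohort multiomics data (and methodologists
studying unsupervised feature extraction) who need a pipeline whose every
stage — preprocessing, decomposition, factor selection, feature
selection, overlap validation — is testable without access to cohort
data: the package ships a synthetic-cohort generator that plants known
latent structure, so statistical claims are checked against ground
truth.

## The method

For each chromosome and omics layer $k$ with feature matrix
$x_{i_k j k}$ ($N_k$ features, $M$ subjects), build the linear-kernel
slice and stack the $K$ layers into an $M \times M \times K$ tensor:

$$x_{jj'k} = \sum_{i_k=1}^{N_k} x_{i_k j k}\,x_{i_k j' k}$$

Decompose by higher-order SVD,

$$x_{jj'k} = \sum_{\ell_1}\sum_{\ell_2}\sum_{\ell_3}
G(\ell_1\ell_2\ell_3)\,u_{\ell_1 j}\,u_{\ell_2 j'}\,u_{\ell_3 k},$$

and pick, per chromosome, the subject factor $u_{\ell_1 j}$ that
maximizes the average absolute correlation with the other chromosomes'
factors ("max correlated set"), or that correlates with clinical
covariates ("clinically correlated set"). Back-project the chosen
factors onto features,

$$u_{\ell_1 i_k} = \sum_j x_{i_k j k}\, u_{\ell_1 j},$$

attach $\chi^2$ p-values under a zero-mean Gaussian null,
Benjamini–Hochberg-adjust, and select features with adjusted
$P < 0.01$. Finally, transcription-factor sets derived from different
layers are compared by Fisher's exact test (conditional-MLE odds ratio)
within a universe of ~2000 human TFs.

Expression/methylation enter as signal summed or averaged over fixed
25,000-nt genomic regions (BED-like input); variants as 012 dosage
matrices (VCF or plain TSV). See the methods vignette
(`vignettes/ktdfe-methods.Rmd`) for the model, estimation choices and
limitations.

## Worked example

```r
library(ktdfe)

run <- run_pipeline(simulation_config(seed = 1))
run
#> ktdfe_run: l1 = {2,2,2,2}, mean <rho_chr> = 0.989, selected: expression=40, methylation=40, variant=400

run$metrics
#>         layer n_selected n_planted  tp precision recall
#> 1  expression         40        40  40         1      1
#> 2 methylation         40        40  40         1      1
#> 3     variant        400       400 400         1      1
#> 4      pooled        480       480 480         1      1
```

Reading this: on a simulated cohort (100 subjects, 4 chromosomes,
500 + 500 + 5000 features per chromosome) the second subject factor
($\ell_1 = 2$) was chosen on every chromosome with average cross-
chromosome correlation 0.989 — the planted shared factor — and feature
selection at adjusted $P < 0.01$ recovered exactly the 480 planted
features across the three layers (precision and recall 1.0). The
clinical screen separately flags the factor linked to the simulated
clinical covariates (`run$clinical_screen`).

The overlap-validation stage, on the shipped TF contingency tables:

```r
tf_overlap_fisher()[, c("cell_type", "factor_set", "odds_ratio", "pvalue")]
#>     cell_type            factor_set odds_ratio     pvalue
#> 1 cd4_t_cells        max_correlated   2.698315 0.03141106
#> 2 neutrophils        max_correlated   3.111739 0.04318185
#> 3   monocytes        max_correlated   3.018929 0.02044088
#> 4 cd4_t_cells clinically_correlated   2.450937 0.03366103
#> 5 neutrophils clinically_correlated   2.791547 0.02720317
```

Each row tests whether TFs identified from gene expression overlap the
TFs whose binding sites contain selected genomic variants more than
chance within a 2000-TF universe: odds ratios near 3 with $P < 0.05$
say the two independently derived TF sets agree.

The `analysis/` directory holds the same workflow as numbered scripts
(`01_simulate.R` … `05_overlap.R`), each printing what it found and
writing its tables under `results/`; set `KTDFE_SEED` to change the
seed.

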