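Package: ktdfe
Title: Kernel Tensor Decomposition-Based Unsupervised Feature Extraction
    for Multiomics Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Integrates gene expression, DNA methylation and genomic
    variants measured on the same subjects by building per-chromosome
    subject-by-subject linear-kernel tensors, decomposing them with a
    higher-order singular value decomposition (HOSVD), selecting
    subject-mode factors that are shared across chromosomes or correlate
    with clinical covariates, and back-projecting the chosen factors onto
    features to select genomic regions and variants under a chi-squared
    null with Benjamini-Hochberg false-discovery control. Includes a
    synthetic multiomics cohort generator with planted latent factors for
    end-to-end validation, preprocessing of BED-like signals into
    fixed-width genomic regions and of genotype calls into 012 dosage
    matrices, and Fisher's exact tests for transcription-factor overlap
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
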