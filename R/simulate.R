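#' Configuration for the synthetic multiomics cohort generator
#'
#' Defines a cohort with the statistical structure the kernel-tensor
#' pipeline assumes: two orthogonal subject-level latent factors — a
#' "shared" factor loaded on planted features of every chromosome and
#' every omics layer, and a "clinical" factor loaded on a second planted
#' subset and on clinical covariates — plus layer-appropriate baselines
#' and noise. Defaults emulate a cohort of 100 healthy subjects measured
#' on three omics layers over 4 chromosomes: non-negative expression
#' signal (summed-count scale), methylation percentages in \[0, 100\],
#' and 012 genotype dosages with a fixed background allele frequency.
#'
#' @param M number of subjects.
#' @param C number of chromosomes.
#' @param n_features named vector of per-chromosome feature counts for
#'   layers `expression`, `methylation`, `variant`.
#' @param frac_shared fraction of features per layer loaded on the shared
#'   factor.
#' @param frac_clinical fraction loaded on the clinical factor (variants
#'   carry none by default).
#' @param baseline per-layer baseline level (expression counts,
#'   methylation percent).
#' @param loading_shared effect size per layer: additive loading for
#'   expression/methylation, log-odds slope of the per-subject alternate
#'   allele probability for variants.
#' @param loading_clinical as `loading_shared`, for the clinical factor.
#' @param noise_sd Gaussian noise standard deviation for
#'   expression/methylation (variant noise is binomial sampling).
#' @param background_af fixed alternate-allele frequency of background
#'   variants.
#' @param planted_af baseline alternate-allele frequency of planted
#'   variants (modulated by the shared factor on the log-odds scale).
#' @param n_clinical number of clinical variables; the first
#'   `n_clinical_linked` of them load on the clinical factor with
#'   coefficient `clinical_loading` plus N(0, `clinical_noise_sd`) noise,
#'   the rest are pure noise.
#' @param n_clinical_linked,clinical_loading,clinical_noise_sd see above.
#' @param clip clip expression at 0 and methylation to \[0, 100\] (the
#'   valid ranges of the data classes); disable only to inspect the exact
#'   linear structure.
#' @param bin_size genomic-region width used for region coordinates.
#' @param seed integer seed; fixes every draw (per-chromosome, per-layer
#'   substreams are derived from it, so the generator is reproducible
#'   block by block).
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(M = 100L, C = 4L,
                              n_features = c(expression = 500L,
                                             methylation = 500L,
                                             variant = 5000L),
                              frac_shared = c(expression = 0.02,
                                              methylation = 0.02,
                                              variant = 0.02),
                              frac_clinical = c(expression = 0.02,
                                                methylation = 0.02,
                                                variant = 0),
                              baseline = c(expression = 100,
                                           methylation = 50),
                              loading_shared = c(expression = 30,
                                                 methylation = 12,
                                                 variant = 1.5),
                              loading_clinical = c(expression = 10,
                                                   methylation = 4,
                                                   variant = 0),
                              noise_sd = c(expression = 3,
                                           methylation = 2),
                              background_af = 0.3, planted_af = 0.4,
                              n_clinical = 7L, n_clinical_linked = 2L,
                              clinical_loading = 1, clinical_noise_sd = 1,
                              clip = TRUE, bin_size = 25000L, seed = 1L) {
  cfg <- list(M = as.integer(M), C = as.integer(C),
              n_features = n_features, frac_shared = frac_shared,
              frac_clinical = frac_clinical, baseline = baseline,
              loading_shared = loading_shared,
              loading_clinical = loading_clinical, noise_sd = noise_sd,
              background_af = background_af, planted_af = planted_af,
              n_clinical = as.integer(n_clinical),
              n_clinical_linked = as.integer(n_clinical_linked),
              clinical_loading = clinical_loading,
              clinical_noise_sd = clinical_noise_sd,
              clip = isTRUE(clip),
              bin_size = as.integer(bin_size), seed = as.integer(seed))
  stopifnot(cfg$M >= 4L, cfg$C >= 1L, all(cfg$n_features >= 1L),
            all(cfg$frac_shared >= 0), all(cfg$frac_shared < 1),
            all(cfg$frac_clinical >= 0), all(cfg$frac_clinical < 1),
            cfg$background_af > 0, cfg$background_af < 1,
            cfg$planted_af > 0, cfg$planted_af < 1,
            cfg$n_clinical >= 1L,
            cfg$n_clinical_linked <= cfg$n_clinical,
              cfg$bin_size >= 1L)
  structure(cfg, class = "sim_config")
}

sim_layers <- c("expression", "methylation", "variant")

## derived substream seed: reproducible per (chromosome, layer) block
block_seed <- function(seed, c, k) {
  as.integer((as.double(seed) + 1009 * c + 101 * k) %% 2147483645L) + 1L
}

#' Simulate a multiomics cohort with planted latent structure
#'
#' Draws the two latent factors (Gaussian, Gram-Schmidt-orthogonalized
#' against the constant vector and each other, scaled to unit variance
#' across subjects), then for every chromosome and layer generates:
#' expression/methylation as `baseline + a_i * factor + noise` on planted
#' rows (with a random sign per feature) and pure baseline + noise
#' elsewhere, clipped to the layer's valid range; genotype dosages as
#' binomial(2, p) draws where planted variants' log-odds follow the
#' shared factor and background variants use a fixed allele frequency.
#' Clinical variables are linear in the clinical factor plus noise. The
#' same latent factors are used on every chromosome — that cross-
#' chromosome consistency is exactly what the factor-selection stage
#' exploits.
#'
#' @param config a [simulation_config()].
#' @return A list of class `multiomics_sim`: `layers` (per chromosome, a
#'   named list of [omics_matrix()] for the three layers), `clinical`
#'   (data.frame, subjects x variables), and `truth` (latent factor
#'   vectors, planted feature IDs and signed loadings per chromosome and
#'   layer, linked clinical variable names, and the config).
#' @export
simulate_multiomics <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  M <- config$M; C <- config$C
  subject_ids <- sprintf("S%03d", seq_len(M))
  chroms <- paste0("chr", seq_len(C))
  set.seed(config$seed)
  f_shared <- latent_factor(M)
  f_clin <- latent_factor(M, orth_to = f_shared)
  planted <- list()
  layers <- list()
  clipped <- 0; signal_cells <- 0
  for (ci in seq_len(C)) {
    chrom <- chroms[ci]
    layers[[chrom]] <- list()
    planted[[chrom]] <- list()
    for (ki in seq_along(sim_layers)) {
      lay <- sim_layers[ki]
      N <- as.integer(config$n_features[[lay]])
      set.seed(block_seed(config$seed, ci, ki))
      n_sh <- round(config$frac_shared[[lay]] * N)
      n_cl <- round(config$frac_clinical[[lay]] * N)
      idx_sh <- sort(sample.int(N, n_sh))
      idx_cl <- sort(sample.int(N, n_cl, prob = as.numeric(!seq_len(N) %in% idx_sh)))
      sign_sh <- sample(c(-1, 1), n_sh, replace = TRUE)
      sign_cl <- sample(c(-1, 1), n_cl, replace = TRUE)
      if (lay == "variant") {
        pos <- sort(sample.int(5000000L, N))
        ids <- sprintf("%s:%d", chrom, pos)
        vals <- matrix(stats::rbinom(N * M, 2L, config$background_af), N, M)
        g <- config$loading_shared[["variant"]]
        for (r in seq_along(idx_sh)) {
          p <- stats::plogis(stats::qlogis(config$planted_af) +
                               sign_sh[r] * g * f_shared)
          vals[idx_sh[r], ] <- stats::rbinom(M, 2L, p)
        }
        if (n_cl > 0L) {
          gc_ <- config$loading_clinical[["variant"]]
          for (r in seq_along(idx_cl)) {
            p <- stats::plogis(stats::qlogis(config$planted_af) +
                                 sign_cl[r] * gc_ * f_clin)
            vals[idx_cl[r], ] <- stats::rbinom(M, 2L, p)
          }
        }
        a_sh <- sign_sh * g
        a_cl <- sign_cl * config$loading_clinical[["variant"]]
      } else {
        starts <- (seq_len(N) - 1) * config$bin_size
        ids <- sprintf("%s:%d-%d", chrom, as.integer(starts),
                       as.integer(starts + config$bin_size))
        vals <- config$baseline[[lay]] +
          matrix(stats::rnorm(N * M, sd = config$noise_sd[[lay]]), N, M)
        a_sh <- sign_sh * config$loading_shared[[lay]]
        a_cl <- sign_cl * config$loading_clinical[[lay]]
        vals[idx_sh, ] <- vals[idx_sh, ] + outer(a_sh, f_shared)
        if (n_cl > 0L)
          vals[idx_cl, ] <- vals[idx_cl, ] + outer(a_cl, f_clin)
        if (config$clip) {
          lo <- 0
          hi <- if (lay == "methylation") 100 else Inf
          nclip <- sum(vals < lo | vals > hi)
          clipped <- clipped + nclip
          signal_cells <- signal_cells + length(vals)
          vals <- pmin(pmax(vals, lo), hi)
        }
      }
      layers[[chrom]][[lay]] <- omics_matrix(vals, layer = lay,
                                             chrom = chrom,
                                             feature_ids = ids,
                                             subject_ids = subject_ids)
      planted[[chrom]][[lay]] <- list(
        shared = ids[idx_sh], clinical = ids[idx_cl],
        loading_shared = stats::setNames(a_sh, ids[idx_sh]),
        loading_clinical = stats::setNames(a_cl, ids[idx_cl]))
    }
  }
  if (signal_cells > 0 && clipped / signal_cells > 0.05)
    warning(sprintf(
      "clipping affected %.1f%% of signal cells: baseline too small for the configured loadings",
      100 * clipped / signal_cells))
  set.seed(block_seed(config$seed, 0L, 99L))
  clin_names <- c("glycoalbumin", "cystatin_c", "blood_sugar", "hba1c",
                  "red_blood_cells", "hemoglobin", "hematocrit")
  if (config$n_clinical > length(clin_names))
    clin_names <- c(clin_names,
                    paste0("clinical_", seq_len(config$n_clinical -
                                                  length(clin_names))))
  clin_names <- clin_names[seq_len(config$n_clinical)]
  linked <- clin_names[seq_len(config$n_clinical_linked)]
  clinical <- as.data.frame(stats::setNames(lapply(clin_names, function(nm) {
    base <- stats::rnorm(M, sd = config$clinical_noise_sd)
    if (nm %in% linked) base + config$clinical_loading * f_clin else base
  }), clin_names))
  rownames(clinical) <- subject_ids
  structure(
    list(layers = layers, clinical = clinical,
         truth = list(f_shared = f_shared, f_clinical = f_clin,
                      planted = planted, clinical_linked = linked,
                      config = config)),
    class = "multiomics_sim"
  )
}

## standard-normal factor over subjects, orthogonalized against the
## constant vector (and optionally a previous factor), unit variance
latent_factor <- function(M, orth_to = NULL) {
  z <- stats::rnorm(M)
  z <- z - mean(z)
  if (!is.null(orth_to)) {
    o <- orth_to - mean(orth_to)
    z <- z - sum(z * o) / sum(o * o) * o
  }
  z / stats::sd(z)
}

#' @export
print.multiomics_sim <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf("multiomics_sim: M=%d subjects, C=%d chromosomes, layers: %s\n",
              cfg$M, cfg$C,
              paste(sprintf("%s(%d)", names(cfg$n_features),
                            cfg$n_features), collapse = ", ")))
  invisible(x)
}

#' Precision and recall of a feature selection against planted truth
#'
#' @param selected named list per layer of selected feature IDs (as
#'   returned in `select_features()$selected`).
#' @param truth the `truth` element of a [simulate_multiomics()] result
#'   (or the full `multiomics_sim`).
#' @param target which planted sets count as true: `"shared"` (default)
#'   or `"clinical"`.
#' @return data.frame with one row per layer plus a `pooled` row:
#'   `n_selected`, `n_planted`, `tp`, `precision` (NA when nothing was
#'   selected), `recall`.
#' @export
recovery_metrics <- function(selected, truth, target = c("shared", "clinical")) {
  target <- match.arg(target)
  if (inherits(truth, "multiomics_sim")) truth <- truth$truth
  planted_by_layer <- list()
  for (chrom in names(truth$planted))
    for (lay in names(truth$planted[[chrom]]))
      planted_by_layer[[lay]] <- c(planted_by_layer[[lay]],
                                   truth$planted[[chrom]][[lay]][[target]])
  lays <- union(names(planted_by_layer), names(selected))
  row_for <- function(sel, pl) {
    tp <- length(intersect(sel, pl))
    data.frame(n_selected = length(sel), n_planted = length(pl), tp = tp,
               precision = if (length(sel)) tp / length(sel) else NA_real_,
               recall = if (length(pl)) tp / length(pl) else NA_real_)
  }
  out <- do.call(rbind, lapply(lays, function(lay)
    cbind(layer = lay,
          row_for(unique(selected[[lay]]), unique(planted_by_layer[[lay]])))))
  pooled <- row_for(unique(unlist(selected)),
                    unique(unlist(planted_by_layer)))
  rbind(out, cbind(layer = "pooled", pooled))
}

#' Write a simulated cohort in the formats the preprocessing stage reads
#'
#' Expression and methylation go out as one BED file per subject per
#' chromosome (regions as intervals); genotypes as one 012 TSV per
#' chromosome; clinical covariates as one TSV. Intended for small
#' configurations (round-trip validation of the readers).
#'
#' @param sim a `multiomics_sim`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "multiomics_sim"))
  for (chrom in names(sim$layers)) {
    for (lay in names(sim$layers[[chrom]])) {
      om <- sim$layers[[chrom]][[lay]]
      if (lay == "variant") {
        dir.create(file.path(dir, lay), recursive = TRUE, showWarnings = FALSE)
        d <- data.frame(variant_id = om$feature_ids, om$values,
                        check.names = FALSE)
        utils::write.table(d, file.path(dir, lay, paste0(chrom, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      } else {
        sub <- file.path(dir, lay, chrom)
        dir.create(sub, recursive = TRUE, showWarnings = FALSE)
        coords <- do.call(rbind, strsplit(sub("^.*:", "", om$feature_ids), "-"))
        for (j in seq_along(om$subject_ids)) {
          d <- data.frame(chrom = chrom, start = as.integer(coords[, 1L]),
                          end = as.integer(coords[, 2L]),
                          value = om$values[, j])
          utils::write.table(d,
                             file.path(sub, paste0(om$subject_ids[j], ".bed")),
                             sep = "\t", quote = FALSE, row.names = FALSE,
                             col.names = FALSE)
        }
      }
    }
  }
  utils::write.table(
    data.frame(subject_id = rownames(sim$clinical), sim$clinical),
    file.path(dir, "clinical.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
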