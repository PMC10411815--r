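#' Run the full kernel-tensor feature-extraction pipeline
#'
#' Orchestrates one reproducible end-to-end run on a simulated cohort:
#' simulate, build the per-chromosome kernel tensors, decompose them by
#' HOSVD, choose the max-correlated factor set (and, from the clinical
#' screen, a clinically correlated set when one exists), score and select
#' features per layer, test pairwise cross-chromosome correlations, and
#' score the selection against the planted ground truth. Identical
#' config and seed give an identical manifest (timings aside).
#'
#' @param config a [simulation_config()]; all randomness flows from its
#'   `seed`.
#' @param candidates candidate \eqn{\ell_1} indices for factor selection.
#' @param alpha feature-selection threshold on adjusted p-values.
#' @param clinical_alpha flag threshold for the clinical screen.
#' @param pair_thresholds thresholds for chromosome-pair counting.
#' @param output_dir if non-NULL, per-layer score tables, the correlation
#'   report and a JSON manifest are written there.
#' @param verbose log stage progress and counts to stderr.
#' @return List of class `ktdfe_run`: `manifest` (config, chosen factors,
#'   per-layer selection counts, clinically correlated factors, package
#'   version), `selection` (the max-correlated [choose_max_correlated_factors()]
#'   result), `pair_report`, `clinical_screen`, `scores` (per-set pooled
#'   [select_features()] results), `metrics` (recovery vs. planted truth)
#'   and the simulated `sim` object.
#' @export
run_pipeline <- function(config = simulation_config(), candidates = 2:5,
                         alpha = 0.01, clinical_alpha = 0.05,
                         pair_thresholds = c(0.01, 0.05),
                         output_dir = NULL, verbose = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    t1 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t1, 3)
    res
  }

  sim <- stage("simulate", simulate_multiomics(config))
  say("simulated %d chromosomes x %d layers", config$C,
      length(sim$layers[[1L]]))

  factors <- stage("decompose", lapply(sim$layers, function(lys)
    hosvd(build_kernel_tensor(lys))))

  sel <- stage("select_factors",
               choose_max_correlated_factors(factors, candidates))
  say("max-correlated set: l1 = {%s}, mean <rho_chr> = %.3f",
      paste(sel$chosen, collapse = ","), mean(sel$rho_chr))

  pair_report <- stage("pair_tests",
                       count_significant_pairs(sel$vectors, pair_thresholds))

  ref_chrom <- names(which.max(sel$rho_chr))
  clin <- stage("clinical_screen",
                clinical_correlation_screen(factors[[ref_chrom]],
                                            sim$clinical, candidates,
                                            alpha = clinical_alpha))
  say("clinical screen (reference %s): flagged l1 = {%s}", ref_chrom,
      paste(clin$flagged_l1, collapse = ","))

  score_set <- function(chosen_by_chrom) {
    tabs <- list()
    for (chrom in names(sim$layers)) {
      u <- extract_subject_factors(factors[[chrom]],
                                   chosen_by_chrom[[chrom]], chrom)
      for (lay in names(sim$layers[[chrom]]))
        tabs[[paste(chrom, lay, sep = ".")]] <-
          feature_scores(sim$layers[[chrom]][[lay]], u, alpha = alpha)
    }
    select_features(tabs, alpha = alpha)
  }
  scores <- list()
  scores$max_correlated <- stage("score_max",
                                 score_set(as.list(sel$chosen)))
  clinical_l1 <- if (length(clin$flagged_l1)) {
    ft <- clin$table[clin$table$flagged, ]
    ft$l1[which.min(ft$p_adj)]
  } else integer(0)
  if (length(clinical_l1)) {
    fixed <- stats::setNames(rep(clinical_l1, config$C), names(sim$layers))
    scores$clinically_correlated <- stage("score_clinical",
                                          score_set(as.list(fixed)))
  }

  metrics <- stage("recovery", recovery_metrics(
    scores$max_correlated$selected, sim$truth, target = "shared"))

  n_sel <- vapply(scores$max_correlated$selected, length, integer(1L))
  say("selected features (max set): %s",
      paste(sprintf("%s=%d", names(n_sel), n_sel), collapse = ", "))
  manifest <- list(
    package = "ktdfe",
    version = as.character(utils::packageVersion("ktdfe")),
    config = unclass(config),
    candidates = candidates,
    alpha = alpha,
    chosen_max_correlated = as.list(sel$chosen),
    rho_chr = as.list(round(sel$rho_chr, 6)),
    reference_chrom = ref_chrom,
    clinically_correlated_l1 = clinical_l1,
    n_selected = as.list(n_sel),
    pair_counts = pair_report$counts,
    timings = as.list(timings),
    total_seconds = round(proc.time()[["elapsed"]] - t0, 3)
  )
  out <- structure(list(manifest = manifest, selection = sel,
                        pair_report = pair_report, clinical_screen = clin,
                        scores = scores, metrics = metrics, sim = sim,
                        factors = factors),
                   class = "ktdfe_run")
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    for (set in names(scores))
      utils::write.table(scores[[set]]$table,
                         file.path(output_dir, paste0("scores_", set, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(pair_report$pairs,
                       file.path(output_dir, "chromosome_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(clin$table,
                       file.path(output_dir, "clinical_screen.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' @export
print.ktdfe_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("ktdfe_run: l1 = {%s}, mean <rho_chr> = %.3f, selected: %s\n",
              paste(unlist(m$chosen_max_correlated), collapse = ","),
              mean(unlist(m$rho_chr)),
              paste(sprintf("%s=%d", names(m$n_selected),
                            unlist(m$n_selected)), collapse = ", ")))
  invisible(x)
}
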