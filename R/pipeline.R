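#' Pipeline configuration
#'
#' Bundles every stage's tunables with a single master seed from which all
#' stage seeds are derived deterministically.
#'
#' @param extraction An [extraction_config()].
#' @param n_perm,percentile Parallel-analysis settings.
#' @param n_pcs_boot Components used in bootstrap replicates; `NULL` means
#'   "use the parallel-analysis result".
#' @param k Cluster count, or `"auto"` to require elbow/consensus agreement.
#' @param k_range,n_resamples Consensus-clustering settings.
#' @param bootstrap_B Bootstrap resamples for stability.
#' @param sigma_grid,noise_reps,noise_domain Noise-sensitivity settings.
#' @param r_threshold,alpha,fdr,boruta_iter Selection-cascade settings.
#' @param entry_p,stay_p Stepwise-regression thresholds.
#' @param seed Master seed.
#' @return `oct_pipeline_config` list.
#' @export
pipeline_config <- function(extraction = reduced_extraction_config(),
                            n_perm = 200, percentile = 95,
                            n_pcs_boot = NULL,
                            k = "auto", k_range = 2:6, n_resamples = 50,
                            bootstrap_B = 100,
                            sigma_grid = c(0, 0.5, 1, 2), noise_reps = 5,
                            noise_domain = "feature",
                            r_threshold = 0.8, alpha = 0.05, fdr = FALSE,
                            boruta_iter = 100,
                            entry_p = 0.1, stay_p = 0.05, seed = 1) {
  structure(as.list(environment()), class = "oct_pipeline_config")
}

#' Run the full analysis pipeline on a cohort
#'
#' Orchestrates every stage end to end: feature extraction, z-scoring, PCA
#' with parallel-analysis retention, cluster-number selection (elbow and
#' consensus must agree under `k = "auto"`, otherwise the consensus choice
#' wins with a warning), hybrid clustering, bootstrap and noise stability,
#' the selection cascade and stepwise logistic models for both endpoints
#' (residual/recurrent edema; poor vision), and cluster-wise clinical
#' comparisons. When `out_dir` is given, per-stage CSV/JSON outputs and a
#' short markdown report are written.
#'
#' @param cohort An `oct_cohort` (e.g. from [generate_cohort()]).
#' @param config An [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return `oct_pipeline_result` list with all stage objects.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "oct_pipeline_config"))
  seed <- config$seed
  features <- extract_cohort(cohort, config$extraction)
  z <- suppressWarnings(zscore_features(features))
  pa <- parallel_analysis(z, n_perm = config$n_perm,
                          percentile = config$percentile, seed = seed + 1)
  n_pcs <- max(pa$n_retained, 2L)
  pca <- fit_pca(z)
  scores <- as.matrix(z) %*% pca$loadings[, seq_len(n_pcs), drop = FALSE]

  if (identical(config$k, "auto")) {
    el <- elbow_select_k(scores, seed = seed + 2)
    cs <- consensus_select_k(scores, k_range = config$k_range,
                             n_resamples = config$n_resamples,
                             seed = seed + 3)
    if (el$k != cs$k) {
      warning(sprintf("elbow (k=%d) and consensus (k=%d) disagree; %s",
                      el$k, cs$k, "using the consensus choice"))
    }
    k <- cs$k
  } else {
    k <- config$k; el <- NULL; cs <- NULL
  }
  clusters <- hybrid_cluster(scores, k, seed = seed + 4)

  n_pcs_boot <- if (is.null(config$n_pcs_boot)) n_pcs else config$n_pcs_boot
  stab <- bootstrap_stability(features, clusters$labels, n_pcs = n_pcs_boot,
                              k = k, B = config$bootstrap_B, seed = seed + 5)
  noise <- noise_sensitivity(features, config$sigma_grid,
                             reps = config$noise_reps,
                             domain = config$noise_domain, k = k,
                             n_pcs = n_pcs_boot, seed = seed + 6)

  clin <- cohort$clinical
  selections <- list(); models <- list()
  for (oc in c("rdme", "vision_poor")) {
    sel <- select_features(features, clusters$labels, clin[[oc]],
                           r_threshold = config$r_threshold,
                           alpha = config$alpha, fdr = config$fdr,
                           max_iter = config$boruta_iter, seed = seed + 7)
    cand <- sel$stage3_confirmed
    mod <- if (length(cand)) {
      backward_stepwise_logistic(features[, cand, drop = FALSE], clin[[oc]],
                                 entry_p = config$entry_p,
                                 stay_p = config$stay_p)
    } else NULL
    selections[[oc]] <- sel
    models[[oc]] <- mod
  }
  comparisons <- compare_clusters(
    clin[, intersect(c("age", "dm_duration", "hba1c", "cmt_baseline_um",
                       "bcva_logmar_baseline", "sex", "dr_stage",
                       "medication", "rdme", "vision_poor"), names(clin))],
    clusters$labels
  )
  result <- structure(list(
    features = features, parallel = pa, pca = pca, n_pcs = n_pcs,
    scores = scores, elbow = el, consensus = cs, k = k,
    clusters = clusters, stability = stab, noise = noise,
    selections = selections, models = models, comparisons = comparisons,
    config = config
  ), class = "oct_pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(result, cohort, out_dir)
  result
}

write_pipeline_outputs <- function(result, cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cbind(eye_id = rownames(result$features), result$features),
                   file.path(out_dir, "features.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(eye_id = rownames(result$features),
               cluster = result$clusters$labels),
    file.path(out_dir, "clusters.csv"), row.names = FALSE)
  utils::write.csv(result$noise, file.path(out_dir, "noise_curve.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(
    n_pcs = result$n_pcs,
    explained = sum(result$pca$explained[seq_len(result$n_pcs)]),
    k = result$k,
    bootstrap_ari_mean = result$stability$mean,
    bootstrap_ari_sd = result$stability$sd,
    confirmed_rdme = result$selections$rdme$stage3_confirmed,
    confirmed_vision = result$selections$vision_poor$stage3_confirmed,
    seed = result$config$seed
  ), file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  rep <- c(
    "# Pipeline report",
    sprintf("- eyes: %d, features: %d", nrow(result$features),
            ncol(result$features)),
    sprintf("- retained components (parallel analysis): %d", result$n_pcs),
    sprintf("- clusters: k = %d (sizes %s)", result$k,
            paste(table(result$clusters$labels), collapse = "/")),
    sprintf("- bootstrap ARI: %.2f +/- %.2f", result$stability$mean,
            result$stability$sd),
    sprintf("- confirmed RDME features: %s",
            paste(result$selections$rdme$stage3_confirmed, collapse = ", "))
  )
  writeLines(rep, file.path(out_dir, "report.md"))
  invisible(NULL)
}
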