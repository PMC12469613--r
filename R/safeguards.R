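# Guardrails against overparameterisation, and the end-to-end pipeline.

#' Validate a user configuration into a guarded run plan
#'
#' Enforces the hard caps (at most 150 features, 5 subtypes, 6 stages, at
#' least 5 biomarkers per cluster) and the soft default of 10 biomarkers per
#' cluster, and derives `M_min = n_stages * min_cluster`, the minimum number
#' of biomarkers needed to populate every stage-cluster.
#'
#' @param max_features Maximum features retained by selection (<= 150).
#' @param n_subtypes Number of subtypes (<= 5).
#' @param n_stages Number of stages (<= 6).
#' @param min_cluster Minimum biomarkers per stage-cluster (>= 5); `NULL`
#'   defaults to 10.
#' @param em_iters,mcmc_burnin,mcmc_final,seed,tol Passed to [ebm_config()].
#' @return An `eb_run_plan`: the validated `eb_config`, `max_features`,
#'   `M_min`, and any warnings.
#' @export
validate_config <- function(max_features = 150L, n_subtypes = 1L,
                            n_stages = 4L, min_cluster = NULL,
                            em_iters = 100L, mcmc_burnin = 10000L,
                            mcmc_final = 100000L, seed = 42L, tol = 1e-4) {
  if (max_features > 150L)
    eb_abort("eb_config_error",
             "max_features exceeds the hard cap of 150 features")
  if (max_features < 1L)
    eb_abort("eb_config_error", "max_features must be at least 1")
  if (n_subtypes > 5L)
    eb_abort("eb_config_error", "n_subtypes exceeds the maximum of 5 subtypes")
  if (n_subtypes < 1L)
    eb_abort("eb_config_error", "n_subtypes must be at least 1")
  if (n_stages > 6L)
    eb_abort("eb_config_error", "n_stages exceeds the maximum of 6 stages")
  if (n_stages < 1L)
    eb_abort("eb_config_error", "n_stages must be at least 1")
  if (is.null(min_cluster)) min_cluster <- 10L
  if (min_cluster < 5L)
    eb_abort("eb_config_error",
             "min_cluster is below the minimum allowed cluster size of 5")
  M_min <- as.integer(n_stages) * as.integer(min_cluster)
  if (M_min > max_features)
    eb_abort("eb_config_error", sprintf(
      "n_stages * min_cluster (%d) exceeds max_features (%d)",
      M_min, max_features))
  cfg <- ebm_config(n_subtypes = n_subtypes, n_stages = n_stages,
                    min_cluster = min_cluster, em_iters = em_iters,
                    mcmc_burnin = mcmc_burnin, mcmc_final = mcmc_final,
                    seed = seed, tol = tol)
  structure(list(config = cfg, max_features = as.integer(max_features),
                 M_min = M_min, warnings = character(0)),
            class = "eb_run_plan")
}

#' Merge sparsely populated subtypes
#'
#' Any subtype with fewer than `threshold` MAP-assigned subjects is merged
#' into the last (highest-index) subtype meeting the threshold: its
#' responsibility mass and mixture weight are reassigned and K is reduced. If
#' every subtype is sparse the model collapses to a single subtype. A warning
#' lists the merged subtypes. Orderings are not refit after the merge; the
#' posterior is renormalised as-is.
#'
#' @param model An `eb_model`.
#' @param assignments MAP assignment table from [assign_subjects()].
#' @param threshold Minimum subjects per subtype (default 10).
#' @return List with the merged `model`, refreshed `assignments`, and
#'   `merged` (indices of the subtypes that were absorbed, empty if none).
#' @export
merge_sparse_subtypes <- function(model, assignments, threshold = 10L) {
  K <- length(model$partitions)
  counts <- tabulate(assignments$Subtype, K)
  sparse <- which(counts < threshold)
  if (!length(sparse) || K == 1L)
    return(list(model = model, assignments = assignments, merged = integer(0)))
  valid <- which(counts >= threshold)
  if (length(valid)) {
    target <- max(valid)
    keep <- sort(valid)
  } else {
    target <- which.max(counts)  # all sparse: collapse to the largest
    keep <- target
    sparse <- setdiff(seq_len(K), target)
  }
  eb_warning("eb_subtype_merge_warning", paste0(
    "merging sparsely populated subtype(s) ",
    paste(sparse, collapse = ", "), " (fewer than ", threshold,
    " subjects) into subtype ", target), merged = sparse, target = target)
  r <- model$posterior
  for (k in sparse) {
    r[, target, ] <- r[, target, ] + r[, k, ]
  }
  r <- r[, keep, , drop = FALSE]
  pi <- model$pi
  pi[target] <- pi[target] + sum(pi[sparse])
  pi <- pi[keep]
  model$posterior <- r
  model$pi <- pi / sum(pi)
  model$partitions <- model$partitions[keep]
  model$config$n_subtypes <- length(keep)
  assignments <- assign_subjects(model)
  list(model = model, assignments = assignments, merged = sparse)
}

#' Stage set retained for visualisation
#'
#' A stage is excluded from plots (model objects are untouched) if and only
#' if it holds fewer than three subjects *and* only a single outcome class.
#'
#' @param assignments MAP assignment table.
#' @return Integer vector of retained stages; the dropped stages are in
#'   attribute `"dropped"`.
#' @export
filter_sparse_stages <- function(assignments) {
  stages <- sort(unique(assignments$Stage))
  drop <- vapply(stages, function(s) {
    rows <- assignments$Stage == s
    sum(rows) < 3L && length(unique(assignments$Outcome[rows])) == 1L
  }, logical(1))
  structure(stages[!drop], dropped = stages[drop])
}

#' Run the full pipeline end to end
#'
#' Readiness, (conditional) ensemble feature selection, guarded model fit,
#' safeguard merging, MCMC positional confidence, evaluation, and artifact
#' export. All randomness is keyed to `plan$config$seed` (the selection
#' ensemble uses `selection_seed`, default 42, incremented per fold), so
#' same-seed reruns produce byte-identical CSV artifacts.
#'
#' @param data_path,meta_path Input tables (CSV/TSV/PSV).
#' @param out_dir Output directory for artifacts; created if needed.
#' @param plan An `eb_run_plan` from [validate_config()].
#' @param outcome_order Optional ordered outcome labels.
#' @param baseline Optional baseline class label.
#' @param selection_seed Base seed for the selection ensemble (default 42).
#' @param make_plots Render PNG figures (default TRUE).
#' @param quiet Suppress progress messages.
#' @return Invisibly, an `eb_artifacts` list: `cohort`, `selection`, `model`,
#'   `assignments`, `confidence`, `evaluation`, `readiness_report`, `files`.
#' @export
run_pipeline <- function(data_path, meta_path, out_dir,
                         plan = validate_config(),
                         outcome_order = NULL, baseline = NULL,
                         selection_seed = 42L, make_plots = TRUE,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) eb_info(...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, mode = 2L) != 0L)
    eb_abort("eb_format_error",
             sprintf("output directory '%s' is not writable", out_dir))

  say("[readiness] validating and preprocessing inputs")
  rd <- run_readiness(data_path, meta_path, outcome_order = outcome_order,
                      baseline = baseline)
  cohort <- rd$cohort

  say("[selection] ensemble stability-scored feature selection")
  sel_cfg <- selection_config(U_max = plan$max_features,
                              base_seed = selection_seed)
  selection <- maybe_skip_selection(cohort, sel_cfg, M_min = plan$M_min)
  say(sprintf("[selection] %d features retained (scenario: %s)",
              length(selection$selected), selection$scenario))
  model_cohort <- subset_cohort(cohort, selection$selected)

  say("[model] fitting the event-based model by EM")
  model <- run_em(model_cohort, plan$config)
  assignments <- assign_subjects(model)

  merged <- merge_sparse_subtypes(model, assignments)
  model <- merged$model
  assignments <- merged$assignments

  say("[model] sampling biomarker orderings (MCMC)")
  confidence <- run_mcmc(model)

  say("[evaluation] classification report and stage-separation tests")
  evaluation <- list(
    classification = classification_report(model_cohort,
                                           seed = selection_seed),
    chi2 = chi2_stage_separation(assignments)
  )

  files <- export_annotations(assignments, confidence, out_dir)
  files$stability_table <- file.path(out_dir, "stability_table.csv")
  utils::write.csv(selection$table, files$stability_table, row.names = FALSE)
  files$classification_report <- file.path(out_dir,
                                           "classification_report.csv")
  utils::write.csv(evaluation$classification$report,
                   files$classification_report, row.names = FALSE)
  files$chi2_results <- file.path(out_dir, "chi2_results.csv")
  utils::write.csv(evaluation$chi2, files$chi2_results, row.names = FALSE)
  if (make_plots) {
    kept <- filter_sparse_stages(assignments)
    files$stage_distribution <- plot_stage_distribution(assignments, kept,
                                                        out_dir)
    files$heatmap <- plot_heatmap(model_cohort, assignments, out_dir)
    files$positional_confidence <- plot_positional_confidence(confidence,
                                                              out_dir)
  }
  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(c(
    sprintf("seed: %d", plan$config$seed),
    sprintf("selection_seed: %d", selection_seed),
    sprintf("subtypes: %d  stages: %d  min_cluster: %d",
            plan$config$n_subtypes, plan$config$n_stages,
            plan$config$min_cluster),
    sprintf("max_features: %d  M_min: %d", plan$max_features, plan$M_min),
    sprintf("selection scenario: %s  features: %d", selection$scenario,
            length(selection$selected)),
    sprintf("final log-likelihood: %.6f", utils::tail(model$loglik_trace, 1L))
  ), log_path)
  files$run_log <- log_path
  say("[done] artifacts written to ", out_dir)
  invisible(structure(list(
    cohort = cohort, selection = selection, model = model,
    assignments = assignments, confidence = confidence,
    evaluation = evaluation, readiness_report = rd$report, files = files
  ), class = "eb_artifacts"))
}
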