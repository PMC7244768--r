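# End-to-end pipeline: simulate -> count -> normalize -> train/predict ->
# dge/survival, with provenance (config + checksums) in the output directory.

#' Default pipeline configuration
#'
#' @param seed master RNG seed for every stochastic stage.
#' @param n_per_class simulated samples per subtype.
#' @param n_trees forest size (5000 for the published setup; smaller values
#'   trade vote-probability resolution for speed).
#' @param noise_scale simulator biological noise sigma.
#' @param train_fraction training fraction of the stratified split.
#' @return named list of pipeline settings.
#' @export
run_config <- function(seed = 1L, n_per_class = 40L, n_trees = 500L,
                       noise_scale = 0.6, train_fraction = 2 / 3) {
  list(seed = as.integer(seed), n_per_class = as.integer(n_per_class),
       n_trees = as.integer(n_trees), noise_scale = noise_scale,
       train_fraction = train_fraction)
}

#' Run the full synthetic-data pipeline
#'
#' Simulates a labeled cohort, writes the deduplicated count matrix and QC
#' table, normalizes to gene level, performs the stratified split, trains
#' the subtype forest and predicts the validation cohort, runs the ABC/GCB
#' volcano analysis and a PCA map, and runs the survival analyses
#' (double-expressor calling at the 70th-percentile MYC/BCL2 thresholds,
#' log-rank, multivariate Cox). Every artifact is written under
#' \code{out_dir}; the configuration and an md5 manifest are saved alongside
#' so that a rerun with the same configuration reproduces identical files.
#'
#' @param config list from \code{\link{run_config}}, or path to a YAML file
#'   with the same fields.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the fitted model, the concordance report,
#'   the Cox table and the paths of all artifacts.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- utils::modifyList(run_config(), yaml::read_yaml(config))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  panel <- default_panel()
  paths <- list()

  sim <- simulate_cohort(
    sim_config(n_per_class = config$n_per_class,
               noise_scale = config$noise_scale, seed = config$seed),
    panel = panel)
  paths$counts <- file.path(out_dir, "counts.tsv")
  paths$qc <- file.path(out_dir, "qc.tsv")
  write_counts(sim$counts, paths$counts, paths$qc)

  cohort <- cohort_from_sim(sim, panel)
  paths$expression <- file.path(out_dir, "expression.tsv")
  utils::write.table(
    data.frame(sample_id = cohort$expr$samples, cohort$expr$values,
               check.names = FALSE),
    paths$expression, sep = "\t", quote = FALSE, row.names = FALSE)

  cohort <- split_cohort(cohort, fraction = config$train_fraction,
                         seed = config$seed)
  model <- train_subtype_model(
    cohort, forest_config(n_trees = config$n_trees, seed = config$seed))
  val <- cohort$cohort == "VALIDATION"
  val_expr <- new_expression_matrix(
    cohort$expr$values[val, , drop = FALSE],
    normalization = cohort$expr$normalization, level = cohort$expr$level)
  pred <- predict_subtypes(model, val_expr)
  paths$predictions <- file.path(out_dir, "predictions.tsv")
  utils::write.table(pred, paths$predictions, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  report <- evaluate_predictions(pred, cohort$labels[val])

  dge_groups <- droplevels(cohort$labels[cohort$labels %in% c("ABC", "GCB")])
  dge_expr <- new_expression_matrix(
    cohort$expr$values[names(dge_groups), , drop = FALSE])
  vol <- volcano(dge_expr, dge_groups)
  paths$volcano <- file.path(out_dir, "volcano.tsv")
  utils::write.table(vol, paths$volcano, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pca <- pca_map(dge_expr)
  paths$pca <- file.path(out_dir, "pca_coordinates.tsv")
  utils::write.table(
    data.frame(sample_id = rownames(pca$coordinates), pca$coordinates),
    paths$pca, sep = "\t", quote = FALSE, row.names = FALSE)

  de <- double_expressor(cohort$expr,
                         stats::quantile(cohort$expr$values[, "MYC"], 0.7),
                         stats::quantile(cohort$expr$values[, "BCL2"], 0.7))
  covs <- data.frame(double_expressor = de$flag,
                     abc_subtype = cohort$labels == "ABC",
                     ipi_high = seq_along(de$flag) %% 2 == 0,
                     row.names = names(de$flag))
  records <- simulate_survival(covs, seed = config$seed)
  lr <- logrank_test(records, records$double_expressor)
  cox <- cox_multivariate(records)
  surv_report <- list(
    double_expressor = list(n_positive = de$n_positive, n = de$n,
                            prevalence_pct = de$prevalence_pct),
    logrank = lr,
    cox = cox,
    validation_accuracy_pct = report$accuracy_pct)
  paths$survival <- file.path(out_dir, "survival_report.json")
  jsonlite::write_json(surv_report, paths$survival, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  paths$config <- file.path(out_dir, "run_config.json")
  jsonlite::write_json(config, paths$config, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  artifact_files <- unlist(paths)
  manifest <- data.frame(file = basename(artifact_files),
                         md5 = unname(tools::md5sum(artifact_files)))
  paths$manifest <- file.path(out_dir, "manifest.tsv")
  utils::write.table(manifest, paths$manifest, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  invisible(list(model = model, report = report, cox = cox,
                 survival = surv_report, paths = paths))
}
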