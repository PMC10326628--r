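#' End-to-end run configuration
#'
#' Bundles the per-stage configurations of a full study-design run:
#' generate -> preprocess -> outlier screen -> quantify -> PCA -> split ->
#' grid-search training -> blind-test evaluation.
#'
#' @param generator A [generator_config()].
#' @param preprocess A [preprocess_config()].
#' @param n_components PCA components fed to the classifiers (default 100).
#' @param algorithms Classifier families to train (subset of `"cnn1d"`,
#'   `"svm"`, `"rf"`, `"xgboost"`).
#' @param grids Optional named list of hyperparameter grids overriding
#'   [default_grid()] per algorithm.
#' @param split_ratio Training fraction (default 0.8).
#' @param cv_folds CV folds for the grid search (default 5).
#' @param quantify_test `"wilcox"` or `"welch"` for the group comparison.
#' @param cnn_epochs Training epochs for the CNN backend.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            preprocess = preprocess_config(),
                            n_components = 100,
                            algorithms = c("cnn1d", "svm", "rf", "xgboost"),
                            grids = NULL, split_ratio = 0.8, cv_folds = 5,
                            quantify_test = "wilcox", cnn_epochs = 40,
                            seed = 1) {
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  structure(list(generator = generator, preprocess = preprocess,
                 n_components = n_components, algorithms = algorithms,
                 grids = grids, split_ratio = split_ratio,
                 cv_folds = as.integer(cv_folds),
                 quantify_test = quantify_test,
                 cnn_epochs = as.integer(cnn_epochs),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes every stage of the study design against a generated cohort and
#' returns (and optionally persists) all intermediate artifacts: manifest,
#' quantification ratios and group statistics, the PCA model (fit on the
#' training partition only), per-algorithm trained models, blind-test
#' predictions, evaluation reports, and a summary table comparing the
#' requested algorithms.
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional output directory; when given, all artifacts are
#'   written there (TSV/JSON) together with a machine-readable run log.
#' @param quiet Suppress per-stage progress messages.
#' @return Object of class `raman_run`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  log <- list(seed = config$seed,
              started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              r_version = as.character(getRversion()),
              stages = list())

  say("[generate] %d samples x %d replicates", config$generator$n_samples,
      config$generator$replicates_per_sample)
  cohort <- run_stage("generate", generate_cohort(config$generator))
  log$stages$generate <- list(n_spectra = length(cohort$spectra))

  say("[preprocess] %d spectra", length(cohort$spectra))
  pre <- run_stage("preprocess", preprocess_batch(cohort$spectra,
                                                  config$preprocess))

  say("[outliers] screening")
  scr <- run_stage("outliers", detect_outlier_spectra(pre, config$preprocess))
  kept_ids <- vapply(scr$kept, function(s) s$spectrum_id, character(1))
  manifest <- cohort$manifest[cohort$manifest$spectrum_id %in% kept_ids, ]
  log$stages$outliers <- list(rejected = sum(scr$report$rejected),
                              kept = length(scr$kept))

  say("[quantify] internal-standard ratios")
  ratios <- run_stage("quantify", quant_table(scr$kept))
  stats <- run_stage("quantify", compare_groups(ratios, manifest,
                                                test = config$quantify_test))

  say("[split] ratio %.2f", config$split_ratio)
  split <- run_stage("split", make_split(manifest, ratio = config$split_ratio,
                                         seed = config$seed + 101L))
  tr_rows <- manifest$sample_id %in% split$train
  tr_ids <- manifest$spectrum_id[tr_rows]
  te_ids <- manifest$spectrum_id[!tr_rows]
  keep_by_id <- function(ids) scr$kept[match(ids, kept_ids)]

  say("[features] PCA, %d components (training partition only)",
      config$n_components)
  pca <- run_stage("features",
                   suppressWarnings(fit_pca(keep_by_id(tr_ids),
                                            config$n_components)))
  sc_train <- predict(pca, keep_by_id(tr_ids))
  sc_test <- predict(pca, keep_by_id(te_ids))
  lab_train <- manifest$label[match(tr_ids, manifest$spectrum_id)]
  lab_test <- manifest$label[match(te_ids, manifest$spectrum_id)]
  grp_train <- manifest$sample_id[match(tr_ids, manifest$spectrum_id)]

  models <- list(); preds <- list(); reports <- list()
  summary_rows <- list()
  for (algo in config$algorithms) {
    say("[train] %s", algo)
    grid <- if (!is.null(config$grids[[algo]])) config$grids[[algo]] else NULL
    spec <- classifier_spec(algo, grid = grid, cv_folds = config$cv_folds,
                            seed = config$seed + 211L,
                            cnn_epochs = config$cnn_epochs)
    model <- run_stage(paste0("train:", algo),
                       grid_search_cv(spec, sc_train, lab_train, grp_train))
    p <- predict(model, sc_test)
    p$spectrum_id <- te_ids
    p$sample_id <- manifest$sample_id[match(te_ids, manifest$spectrum_id)]
    p$truth <- lab_test
    cm <- confusion(p$predicted, p$truth)
    rep <- eval_metrics(cm)
    ra <- roc_auc(p$p_pregnancy, p$truth)
    models[[algo]] <- model
    preds[[algo]] <- p
    reports[[algo]] <- list(confusion = cm, metrics = rep, roc = ra)
    summary_rows[[algo]] <- data.frame(
      algorithm = algo, cv_accuracy = model$cv_accuracy,
      test_accuracy = rep$overall_accuracy, correct = rep$correct,
      total = rep$total, auc = ra$auc, stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL
  log$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")

  run <- structure(list(summary = summary, manifest = manifest,
                        ratios = ratios, group_stats = stats, pca = pca,
                        split = split, models = models, predictions = preds,
                        reports = reports, outlier_report = scr$report,
                        config = config, log = log),
                   class = "raman_run")
  if (!is.null(outdir)) persist_run(run, outdir)
  run
}

persist_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_manifest(run$manifest, file.path(outdir, "manifest.tsv"))
  utils::write.table(run$ratios, file.path(outdir, "ratios.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(run$group_stats, file.path(outdir, "group_stats.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(run$outlier_report, file.path(outdir, "outliers.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  save_pca(run$pca, file.path(outdir, "pca.json"))
  for (algo in names(run$predictions)) {
    utils::write.table(
      run$predictions[[algo]][, c("spectrum_id", "sample_id", "p_pregnancy",
                                  "p_non_pregnancy", "predicted", "truth")],
      file.path(outdir, paste0("predictions_", algo, ".tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }
  utils::write.table(run$summary, file.path(outdir, "summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  report <- lapply(run$reports, function(r)
    list(confusion = unclass(r$confusion),
         per_class = r$metrics$per_class,
         overall_accuracy = r$metrics$overall_accuracy,
         correct = r$metrics$correct, total = r$metrics$total,
         auc = r$roc$auc))
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  jsonlite::write_json(run$log, file.path(outdir, "run_log.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(outdir)
}

#' @export
print.raman_run <- function(x, ...) {
  cat(sprintf("<raman_run> %d spectra kept, %d train / %d test samples\n",
              nrow(x$manifest), length(x$split$train), length(x$split$test)))
  cat("\nGroup comparison (internal-standard log ratios):\n")
  gs <- x$group_stats
  gs$p_value <- signif(gs$p_value, 3)
  print(gs, row.names = FALSE)
  cat("\nClassifier comparison (blind test):\n")
  sm <- x$summary
  sm$cv_accuracy <- round(sm$cv_accuracy, 3)
  sm$test_accuracy <- round(sm$test_accuracy, 3)
  sm$auc <- round(sm$auc, 3)
  print(sm, row.names = FALSE)
  invisible(x)
}

#' @export
summary.raman_run <- function(object, ...) object$summary
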