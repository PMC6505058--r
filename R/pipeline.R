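# End-to-end orchestration: simulate a cohort, extract and aggregate
# features, cross-validate the tuned oblique forest per feature set,
# evaluate against the DIS benchmark, and write every intermediate
# artifact plus a manifest. One top-level seed fans out to fixed
# stage-specific seeds (cohort, folds, forest, importance) so stages can
# be re-run independently yet reruns are byte-identical.

#' Pipeline run configuration
#'
#' @param out_dir output directory of the run.
#' @param cohort a [cohort_spec()] describing the synthetic cohort (its
#'   seed is overridden by the derived stage seed).
#' @param feature_sets which per-patient feature sets to model.
#' @param forest an [orf_config()] for tuning.
#' @param k_folds,stratified cross-validation layout.
#' @param bins,min_volume feature-extraction knobs.
#' @param importance_bootstrap bootstrap iterations for the importance
#'   report on the first feature set; 0 skips it.
#' @param seed master seed; stage seeds are derived as seed + 1..4.
#' @return An object of class `run_config` (JSON-serialisable round trip).
#' @export
run_config <- function(out_dir, cohort = cohort_spec(),
                       feature_sets = c("shape", "intensity"),
                       forest = orf_config(), k_folds = 3L,
                       stratified = TRUE, bins = 64L, min_volume = 0,
                       importance_bootstrap = 0L, seed = 1L) {
  feature_sets <- match.arg(feature_sets, c("shape", "intensity", "combined"),
                            several.ok = TRUE)
  structure(list(out_dir = out_dir, cohort = cohort,
                 feature_sets = feature_sets, forest = forest,
                 k_folds = as.integer(k_folds), stratified = stratified,
                 bins = as.integer(bins), min_volume = as.numeric(min_volume),
                 importance_bootstrap = as.integer(importance_bootstrap),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Write / read a run configuration as JSON
#'
#' @param config a [run_config()].
#' @param path JSON file path.
#' @return `read_run_config` returns the `run_config`; the writer returns
#'   the path invisibly. A write/read round trip is identical.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  obj <- unclass(config)
  obj$cohort <- unclass(obj$cohort)
  obj$forest <- unclass(obj$forest)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17), null = "null"),
             path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cohort <- do.call(cohort_spec, obj$cohort[setdiff(names(obj$cohort), character(0))])
  forest <- orf_config(mtry_grid = obj$forest$mtry_grid,
                       ntree_grid = obj$forest$ntree_grid,
                       ridge_grid = obj$forest$ridge_grid,
                       min_node_size = obj$forest$min_node_size,
                       max_depth = obj$forest$max_depth)
  run_config(out_dir = obj$out_dir, cohort = cohort,
             feature_sets = obj$feature_sets, forest = forest,
             k_folds = obj$k_folds, stratified = obj$stratified,
             bins = obj$bins, min_volume = obj$min_volume,
             importance_bootstrap = obj$importance_bootstrap,
             seed = obj$seed)
}

orf_cv_factory <- function(config, fold_seed) {
  force(config); force(fold_seed)
  fold_counter <- new.env()
  fold_counter$i <- 0L
  function(x_train, y_train) {
    fold_counter$i <- fold_counter$i + 1L
    tuned <- orf_tune(x_train, y_train, config,
                      seed = fold_seed + fold_counter$i)
    function(x_test) predict(tuned$forest, x_test)
  }
}

#' Run the full pipeline
#'
#' Simulates the cohort, writes it as NIfTI pairs + `cohort.csv`, reads it
#' back (exercising the disk interface), extracts per-lesion features
#' (`lesions.csv`), aggregates per-patient vectors
#' (`features_<set>.csv`), cross-validates a tuned oblique forest per
#' feature set under a shared fold plan (`predictions_<set>.csv`,
#' `metrics_<set>.json`), evaluates the DIS benchmark
#' (`predictions_dis.csv`, `metrics_dis.json`), compares the first feature
#' set against DIS by McNemar's test, optionally computes the bootstrap
#' importance report, and writes `manifest.json` with seeds, versions and
#' file hashes.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the cohort, feature tables, per-set
#'   metric reports, DIS metrics, the McNemar comparison, and file paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- list(cohort = config$seed + 1L, folds = config$seed + 2L,
                forest = config$seed + 3L, importance = config$seed + 4L)

  cohort <- generate_cohort(config$cohort, seed = seeds$cohort)
  cohort_dir <- file.path(config$out_dir, "cohort")
  write_cohort(cohort, cohort_dir)
  patients <- read_cohort(cohort_dir)

  lesion_tab <- cohort_features(patients, min_volume = config$min_volume,
                                bins = config$bins)
  lesion_tab$converted <- NULL
  write.csv(lesion_tab, file.path(config$out_dir, "lesions.csv"), row.names = FALSE)

  ids <- vapply(patients, `[[`, "", "patient_id")
  y <- as.integer(vapply(patients, `[[`, TRUE, "converted"))
  plan <- fold_plan(y, k = config$k_folds, stratified = config$stratified,
                    seed = seeds$folds)

  reports <- list(); preds <- list()
  for (fs in config$feature_sets) {
    feats <- aggregate_cohort(lesion_tab, fs, patient_ids = ids)
    write.csv(feats, file.path(config$out_dir, paste0("features_", fs, ".csv")),
              row.names = FALSE)
    cv <- cross_validate(feats, y, orf_cv_factory(config$forest, seeds$forest),
                         plan)
    preds[[fs]] <- cv$pred
    pred_df <- data.frame(patient_id = ids, converted = y,
                          predicted = cv$pred, fold = cv$fold)
    write.csv(pred_df, file.path(config$out_dir, paste0("predictions_", fs, ".csv")),
              row.names = FALSE)
    rep <- binary_metrics(confusion_matrix(y, cv$pred))
    reports[[fs]] <- rep
    jsonlite::write_json(
      list(model = fs, confusion = rep$cm[c("TP", "FP", "TN", "FN")],
           metrics = rep$table, flags = rep$flags),
      file.path(config$out_dir, paste0("metrics_", fs, ".json")),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }

  dis <- dis_predict(cohort$table)
  dis <- dis[match(ids, dis$patient_id), ]
  write.csv(dis, file.path(config$out_dir, "predictions_dis.csv"), row.names = FALSE)
  dis_rep <- binary_metrics(confusion_matrix(y, dis$predicted))
  jsonlite::write_json(
    list(model = "dis", confusion = dis_rep$cm[c("TP", "FP", "TN", "FN")],
         metrics = dis_rep$table, flags = dis_rep$flags),
    file.path(config$out_dir, "metrics_dis.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")

  mcn <- mcnemar_test(y, preds[[config$feature_sets[1]]], dis$predicted)

  importance <- NULL
  if (config$importance_bootstrap > 0L) {
    fs1 <- config$feature_sets[1]
    feats <- aggregate_cohort(lesion_tab, fs1, patient_ids = ids)
    importance <- orf_importance(feats, y,
                                 ntree = min(config$forest$ntree_grid),
                                 ridge_grid = config$forest$ridge_grid,
                                 n_bootstrap = config$importance_bootstrap,
                                 seed = seeds$importance)
    write.csv(importance$scores,
              file.path(config$out_dir, "importance.csv"), row.names = FALSE)
  }

  files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(config$out_dir, "manifest.json"))
  manifest <- list(
    package = "cisforest",
    version = as.character(utils::packageVersion("cisforest")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed, stage_seeds = seeds,
    mcnemar_vs_dis = mcn,
    files = data.frame(path = sub(paste0("^", config$out_dir, "/?"), "", files),
                       md5 = unname(tools::md5sum(files))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  invisible(list(cohort = cohort, lesion_table = lesion_tab,
                 fold_plan = plan, reports = reports, dis_report = dis_rep,
                 mcnemar = mcn, importance = importance,
                 out_dir = config$out_dir))
}
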