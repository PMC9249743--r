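# End-to-end pipeline: patient-grouped stratified k-fold cross-validation,
# per-fold CNN training, forest construction, test-set evaluation, and the
# equal-epoch-budget single-CNN baseline.

#' Pipeline configuration
#'
#' @param n_cnns number of feature-extraction CNNs per fold (>= 2;
#'   reference setting 10).
#' @param folds number of cross-validation folds (default 5).
#' @param cnn_spec a [cnn_spec()].
#' @param forest_params a [forest_params()].
#' @param optimizer optional override of `cnn_spec$optimizer`.
#' @param global_seed master seed; every stochastic stage derives its own
#'   stream from it.
#' @param baseline_epoch_budget `"matched"` (baseline trains
#'   `n_cnns * epochs` epochs per fold, the epoch-count analogue of
#'   equal training time) or an explicit integer epoch count.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(n_cnns = 10L, folds = 5L,
                            cnn_spec = cnnforest::cnn_spec(),
                            forest_params = cnnforest::forest_params(),
                            optimizer = NULL, global_seed = 1L,
                            baseline_epoch_budget = "matched") {
  if (n_cnns < 2L) stop("n_cnns must be at least 2")
  if (folds < 2L) stop("folds must be at least 2")
  if (!is.null(optimizer)) cnn_spec$optimizer <- tolower(optimizer)
  structure(list(n_cnns = as.integer(n_cnns), folds = as.integer(folds),
                 cnn_spec = cnn_spec, forest_params = forest_params,
                 global_seed = as.integer(global_seed),
                 baseline_epoch_budget = baseline_epoch_budget),
            class = "pipeline_config")
}

#' Desk-scale pipeline configuration
#'
#' The configuration used throughout the package's tests and examples:
#' 4 CNNs, fivefold CV, 32 x 32 inputs, 2 epochs, 15 trees, Adam.  The
#' mini-batch size is 2, scaling the reference setting proportionally
#' (batch 256 on a ~57k-image fold is ~0.45% of the training set; the
#' desk fold has 384 images per CNN), which preserves the number of
#' optimizer steps per epoch that "2 epochs" implicitly assumes.
#'
#' @param global_seed master seed for the run.
#' @param optimizer optimizer name, default `"adam"`.
#' @return a [pipeline_config()].
#' @export
desk_pipeline_config <- function(global_seed = 1L, optimizer = "adam") {
  pipeline_config(
    n_cnns = 4L, folds = 5L,
    cnn_spec = cnn_spec(input_shape = c(32L, 32L), epochs = 2L,
                        batch_size = 2L, optimizer = optimizer),
    forest_params = forest_params(n_trees = 15L),
    global_seed = global_seed)
}

#' Patient-grouped stratified k-fold assignment
#'
#' Folds are assigned at the patient level (all images of a patient stay
#' together) and stratified by class: per fold, each class's patient
#' count is the floor or ceiling of its share, so class proportions match
#' the cohort's within one patient.
#'
#' @param x a `cohort_dataset`, or a data.frame with columns `patient_id`
#'   and `label` (one row per patient or per image).
#' @param k number of folds.
#' @param rng_seed seed for the patient shuffles.
#' @return a `fold_plan`: list with `k` and `assignment`, a named integer
#'   vector mapping patient id to fold index in `1:k`.
#' @export
stratified_group_kfold <- function(x, k = 5L, rng_seed = 1L) {
  if (inherits(x, "cohort_dataset"))
    x <- data.frame(patient_id = x$patient_id, label = x$label)
  pat <- unique(x[, c("patient_id", "label")])
  if (anyDuplicated(pat$patient_id))
    stop("a patient appears with more than one label")
  assignment <- integer(0)
  with_seed(rng_seed, {
    for (cls in sort(unique(pat$label))) {
      ids <- sample(pat$patient_id[pat$label == cls])
      m <- length(ids)
      if (m < k)
        stop(sprintf("class %s has %d patients, fewer than k = %d",
                     cls, m, k))
      sizes <- rep(m %/% k, k)
      extra <- m %% k
      if (extra > 0L) {
        which_extra <- sample.int(k, extra)
        sizes[which_extra] <- sizes[which_extra] + 1L
      }
      fold_of <- rep(seq_len(k), times = sizes)
      a <- stats::setNames(fold_of, ids)
      assignment <- c(assignment, a)
    }
  })
  structure(list(k = as.integer(k), assignment = assignment),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %d folds, %d patients\n", x$k,
              length(x$assignment)))
  invisible(x)
}

# Split sample ids of a dataset into train/test by fold, asserting zero
# patient overlap.
fold_membership <- function(dataset, plan, fold_index) {
  fold_of <- plan$assignment[dataset$patient_id]
  if (anyNA(fold_of)) stop("dataset contains patients absent from the plan")
  test <- fold_of == fold_index
  train_pat <- unique(dataset$patient_id[!test])
  test_pat <- unique(dataset$patient_id[test])
  if (length(intersect(train_pat, test_pat)))
    stop("patient leakage between train and test structures")
  list(train_ids = dataset$sample_id[!test],
       test_ids = dataset$sample_id[test])
}

#' Run one cross-validation fold of the CNN-feature forest
#'
#' In order: partition the training fold into `n_cnns` class-stratified
#' subsets; train one CNN per subset (trained on the fold minus the
#' subset, validated on the subset); score every training-fold image with
#' every CNN to form the feature matrix P; grow the forest on P; then
#' score the held-out fold and vote.
#'
#' @param dataset a preprocessed `cohort_dataset` (images at the CNN
#'   input shape).
#' @param plan a `fold_plan` covering the dataset's patients.
#' @param fold_index fold to hold out, in `1:plan$k`.
#' @param config a [pipeline_config()].
#' @return list with `forest`, `extractors`, `metrics`, `predictions`
#'   (one row per test image) and `fold_index`.
#' @export
run_fold <- function(dataset, plan, fold_index, config) {
  if (fold_index < 1L || fold_index > plan$k) stop("invalid fold index")
  mem <- fold_membership(dataset, plan, fold_index)
  fk <- mem$train_ids
  ylab <- stats::setNames(dataset$label, dataset$sample_id)
  if (length(unique(ylab[fk])) < 2L || length(unique(ylab[mem$test_ids])) < 1L)
    stop("training fold must contain both classes")
  seed <- config$global_seed
  subsets <- partition_subsets(fk, ylab[fk], config$n_cnns,
                               derive_seed(seed, "subsets", fold_index))
  extractors <- vector("list", config$n_cnns)
  for (i in seq_len(config$n_cnns)) {
    cf_log("fold %d: training CNN %d/%d", fold_index, i, config$n_cnns)
    extractors[[i]] <- train_cnn(setdiff(fk, subsets[[i]]), subsets[[i]],
                                 dataset, config$cnn_spec,
                                 derive_seed(seed, "cnn", fold_index, i))
  }
  P <- build_feature_matrix(extractors, fk, dataset)
  fp <- config$forest_params
  fp$rng_seed <- derive_seed(seed, "forest", fold_index)
  forest <- grow_forest(P, as.integer(ylab[fk]), fp)
  # evaluate on the held-out fold
  Xte <- dataset_matrix(dataset, mem$test_ids, config$cnn_spec$input_shape)
  Pte <- vapply(extractors, function(e) cnn_score_batch(e, Xte),
                numeric(length(mem$test_ids)))
  Pte <- matrix(Pte, nrow = length(mem$test_ids))
  pred <- predict(forest, Pte)
  truth <- as.integer(ylab[mem$test_ids])
  metrics <- compute_metrics(truth, pred$class, pred$vote_fraction)
  predictions <- data.frame(
    sample_id = mem$test_ids,
    patient_id = dataset$patient_id[match(mem$test_ids, dataset$sample_id)],
    label = truth, predicted = pred$class,
    vote_fraction = pred$vote_fraction, fold = fold_index,
    stringsAsFactors = FALSE)
  cf_log("fold %d: accuracy %.3f on %d test images", fold_index,
         metrics$accuracy, metrics$n)
  list(forest = forest, extractors = extractors, metrics = metrics,
       predictions = predictions, fold_index = fold_index)
}

pool_results <- function(per_fold_predictions) {
  all_pred <- do.call(rbind, per_fold_predictions)
  compute_metrics(all_pred$label, all_pred$predicted, all_pred$vote_fraction)
}

#' Run the full cross-validated CNN-feature forest pipeline
#'
#' Builds a patient-grouped stratified fold plan (unless one is given),
#' runs [run_fold()] for every fold, and pools the per-fold confusion
#' tables into one report (per-fold reports are kept alongside).
#'
#' @param dataset a `cohort_dataset`; preprocessed automatically to the
#'   CNN input shape.
#' @param config a [pipeline_config()].
#' @param plan optional pre-built `fold_plan` (shared with the baseline
#'   for paired comparison).
#' @param keep_models keep per-fold forests/extractors in the result
#'   (default `TRUE`).
#' @return a `pipeline_result`: `metrics` (pooled), `per_fold` metric
#'   reports, `predictions` (all test images), `plan`, `config`, `folds`.
#' @export
run_pipeline <- function(dataset, config = pipeline_config(), plan = NULL,
                         keep_models = TRUE) {
  dataset <- preprocess_dataset(dataset, config$cnn_spec$input_shape)
  if (is.null(plan))
    plan <- stratified_group_kfold(dataset, config$folds,
                                   derive_seed(config$global_seed, "folds"))
  folds <- lapply(seq_len(plan$k), function(kk)
    run_fold(dataset, plan, kk, config))
  preds <- lapply(folds, `[[`, "predictions")
  pooled <- pool_results(preds)
  cf_log("pooled accuracy %.3f over %d images", pooled$accuracy, pooled$n)
  structure(list(metrics = pooled,
                 per_fold = lapply(folds, `[[`, "metrics"),
                 predictions = do.call(rbind, preds),
                 plan = plan, config = config,
                 folds = if (keep_models) folds),
            class = "pipeline_result")
}

#' Equal-epoch-budget stand-alone CNN baseline
#'
#' Trains a single CNN per fold on the whole training fold for
#' `n_cnns * epochs` epochs (the epoch-count analogue of giving the
#' baseline the ensemble's total training time), then classifies the
#' held-out fold by the sign of its margin.  Uses the same fold plan as
#' the ensemble for a paired comparison.
#'
#' @param dataset a `cohort_dataset`.
#' @param plan a `fold_plan` (build one with [stratified_group_kfold()]).
#' @param config a [pipeline_config()].
#' @return a `pipeline_result` (no forests; `folds` holds the per-fold
#'   extractor and predictions).
#' @export
run_baseline_cnn <- function(dataset, plan, config = pipeline_config()) {
  dataset <- preprocess_dataset(dataset, config$cnn_spec$input_shape)
  budget <- config$baseline_epoch_budget
  spec <- config$cnn_spec
  spec$epochs <- if (identical(budget, "matched"))
    config$n_cnns * spec$epochs else as.integer(budget)
  spec$select_best_epoch <- FALSE
  ylab <- stats::setNames(dataset$label, dataset$sample_id)
  folds <- lapply(seq_len(plan$k), function(kk) {
    mem <- fold_membership(dataset, plan, kk)
    cf_log("baseline fold %d: training %d epochs", kk, spec$epochs)
    ext <- train_cnn(mem$train_ids, NULL, dataset, spec,
                     derive_seed(config$global_seed, "baseline", kk))
    Xte <- dataset_matrix(dataset, mem$test_ids, spec$input_shape)
    score <- cnn_score_batch(ext, Xte)
    truth <- as.integer(ylab[mem$test_ids])
    pred <- as.integer(score > 0)  # hinge margin decision threshold
    predictions <- data.frame(
      sample_id = mem$test_ids,
      patient_id = dataset$patient_id[match(mem$test_ids,
                                            dataset$sample_id)],
      label = truth, predicted = pred, vote_fraction = score, fold = kk,
      stringsAsFactors = FALSE)
    list(extractor = ext, predictions = predictions,
         metrics = compute_metrics(truth, pred, score), fold_index = kk)
  })
  preds <- lapply(folds, `[[`, "predictions")
  pooled <- pool_results(preds)
  cf_log("baseline pooled accuracy %.3f over %d images",
         pooled$accuracy, pooled$n)
  structure(list(metrics = pooled,
                 per_fold = lapply(folds, `[[`, "metrics"),
                 predictions = do.call(rbind, preds),
                 plan = plan, config = config, folds = folds),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d folds, %d test images pooled\n",
              length(x$per_fold), x$metrics$n))
  print(x$metrics)
  invisible(x)
}

#' Write per-image predictions and metrics of a run to a directory
#'
#' Emits `predictions.tsv` (sample id, patient id, truth, prediction,
#' vote fraction, fold), `metrics.tsv` (pooled and per-fold rows) and
#' `config.json` (the effective configuration).
#'
#' @param result a `pipeline_result`.
#' @param out_dir output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_run_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(result$predictions,
                     file.path(out_dir, "predictions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  rows <- rbind(cbind(scope = "pooled", as.data.frame(result$metrics)),
                do.call(rbind, lapply(seq_along(result$per_fold), function(i)
                  cbind(scope = sprintf("fold%d", i),
                        as.data.frame(result$per_fold[[i]])))))
  utils::write.table(rows, file.path(out_dir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- result$config
  cfg$cnn_spec <- unclass(cfg$cnn_spec)
  cfg$forest_params <- unclass(cfg$forest_params)
  jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(out_dir)
}
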