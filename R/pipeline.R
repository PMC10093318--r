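#' Pipeline configuration
#'
#' One reproducible description of a full run: data source (an image folder
#' or a synthetic spec), the LBP and dense-feature extractor settings, mRMR
#' settings per block, the classifier list and evaluation scheme. Every
#' stage's seed derives deterministically from `seed`.
#'
#' @param input_dir class-per-folder image dataset, or NULL to generate.
#' @param synth_spec a [synthetic_dataset_spec()] used when `input_dir` is
#'   NULL.
#' @param lbp an [lbp_config()].
#' @param deep a [feature_extractor_spec()].
#' @param k_per_block mRMR features kept per block.
#' @param criterion mRMR criterion.
#' @param bins mRMR discretization bins.
#' @param nested_selection if TRUE, mRMR runs inside each training fold
#'   (leak-free); the default selects once on the full matrix before
#'   evaluation, matching the conventional hybrid-pipeline order.
#' @param classifiers character vector of classifier kinds to benchmark.
#' @param scheme an [eval_scheme()].
#' @param output_dir run directory for intermediates and reports.
#' @param seed global seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir = NULL, synth_spec = NULL,
                            lbp = lbp_config(), deep = NULL,
                            k_per_block = 500L, criterion = "MID", bins = 10L,
                            nested_selection = FALSE,
                            classifiers = "svm",
                            scheme = NULL, output_dir = tempfile("urised_run_"),
                            seed = 0L) {
  seed <- as.integer(seed)
  if (is.null(deep)) deep <- feature_extractor_spec(seed = seed + 1L)
  if (is.null(scheme)) scheme <- eval_scheme("kfold_cv", folds = 5L, seed = seed + 2L)
  if (is.null(input_dir) && is.null(synth_spec)) {
    synth_spec <- synthetic_dataset_spec(scale = 0.02, seed = seed + 3L)
  }
  structure(list(input_dir = input_dir, synth_spec = synth_spec, lbp = lbp,
                 deep = deep, k_per_block = as.integer(k_per_block),
                 criterion = criterion, bins = as.integer(bins),
                 nested_selection = nested_selection,
                 classifiers = classifiers, scheme = scheme,
                 output_dir = output_dir, seed = seed),
            class = "pipeline_config")
}

#' Run the full classification pipeline
#'
#' load (or generate) -> LBP block -> dense block -> mRMR per block -> fuse ->
#' train/evaluate each classifier -> report. Every intermediate is written to
#' `config$output_dir` (feature CSVs, selection JSONs, fused CSV, report
#' files) together with a manifest of shapes, seeds and file hashes.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with `results` (per classifier), `fused`,
#'   `manifest_path`, `output_dir`.
#' @export
run_pipeline <- function(config) {
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(fmt, ...) message(sprintf(paste0("[urisedclass] ", fmt), ...))

  records <- if (!is.null(config$input_dir)) {
    load_image_folder(config$input_dir)
  } else {
    generate_dataset(config$synth_spec)
  }
  log_stage("load: %d images, %d classes", length(records),
            length(unique(vapply(records, `[[`, "", "label"))))
  min_class <- min(table(vapply(records, `[[`, "", "label")))
  if (config$scheme$mode == "kfold_cv" && config$scheme$folds > min_class) {
    log_stage("scheme: reducing folds %d -> %d (smallest class)",
              config$scheme$folds, min_class)
    config$scheme$folds <- as.integer(min_class)
  }

  lbp_fm <- extract_lbp_features(records, config$lbp)
  write_features(lbp_fm, file.path(out, "features_lbp.csv"))
  jsonlite::write_json(unclass(config$lbp), file.path(out, "features_lbp.config.json"),
                       auto_unbox = TRUE, digits = NA)
  log_stage("lbp: %d x %d", nrow(lbp_fm$values), ncol(lbp_fm$values))

  deep_fm <- extract_deep_features(records, config$deep)
  write_features(deep_fm, file.path(out, "features_deep.csv"))
  jsonlite::write_json(unclass(config$deep), file.path(out, "features_deep.config.json"),
                       auto_unbox = TRUE, digits = NA)
  log_stage("deep: %d x %d", nrow(deep_fm$values), ncol(deep_fm$values))

  k <- config$k_per_block
  if (k > ncol(lbp_fm$values) || k > ncol(deep_fm$values)) {
    stop(sprintf("select stage: k_per_block = %d exceeds a block width (%d, %d)",
                 k, ncol(lbp_fm$values), ncol(deep_fm$values)))
  }
  sel_a <- mrmr_select(lbp_fm, k, config$criterion, config$bins)
  sel_b <- mrmr_select(deep_fm, k, config$criterion, config$bins)
  write_selection(sel_a, file.path(out, "selection_lbp.json"))
  write_selection(sel_b, file.path(out, "selection_deep.json"))
  log_stage("select: %d per block (%s)", k, config$criterion)

  fused <- fuse(subselect(lbp_fm, sel_a), subselect(deep_fm, sel_b))
  write_features(fused, file.path(out, "features_fused.csv"))
  log_stage("fuse: %d x %d", nrow(fused$values), ncol(fused$values))

  results <- list()
  for (kind in config$classifiers) {
    spec <- classifier_spec(kind, seed = config$seed + 10L)
    results[[kind]] <- if (config$nested_selection) {
      train_eval_nested(lbp_fm, deep_fm, k, config$criterion, config$bins,
                        spec, config$scheme)
    } else {
      train_eval(fused, spec, config$scheme)
    }
    log_stage("train-eval %s: accuracy %.2f%%", kind, results[[kind]]$accuracy)
  }
  render_report(results, out)

  files <- list.files(out, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    seed = config$seed,
    stages = list(lbp = dim(lbp_fm$values), deep = dim(deep_fm$values),
                  fused = dim(fused$values)),
    classifiers = config$classifiers,
    hashes = as.list(tools::md5sum(sort(files))))
  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(list(results = results, fused = fused,
                 manifest_path = manifest_path, output_dir = out))
}

# Leak-free variant: mRMR runs on each training fold only, then the fold's
# selected columns are fused and evaluated on its test rows.
train_eval_nested <- function(lbp_fm, deep_fm, k, criterion, bins, spec, scheme) {
  classes <- sort(unique(lbp_fm$labels))
  folds <- make_folds(lbp_fm, scheme)
  truth <- character(0); preds <- character(0)
  fold_confusions <- list()
  for (fi in seq_along(folds)) {
    fold <- folds[[fi]]
    sub <- function(fm, rows) feature_matrix(fm$values[rows, , drop = FALSE],
                                             fm$sample_ids[rows], fm$labels[rows],
                                             fm$feature_names)
    tr_a <- sub(lbp_fm, fold$train);  te_a <- sub(lbp_fm, fold$test)
    tr_b <- sub(deep_fm, fold$train); te_b <- sub(deep_fm, fold$test)
    sel_a <- mrmr_select(tr_a, k, criterion, bins)
    sel_b <- mrmr_select(tr_b, k, criterion, bins)
    ftr <- fuse(subselect(tr_a, sel_a), subselect(tr_b, sel_b))
    fte <- fuse(subselect(te_a, sel_a), subselect(te_b, sel_b))
    p <- with_seed(spec$seed + 1000L * fi,
                   fit_predict(spec, ftr$values, factor(ftr$labels, levels = classes),
                               fte$values))
    truth <- c(truth, fte$labels)
    preds <- c(preds, as.character(p))
    fold_confusions[[fi]] <- confusion_from_labels(fte$labels, as.character(p), classes)
  }
  cm <- confusion_from_labels(truth, preds, classes)
  list(confusion = cm, fold_confusions = fold_confusions,
       classifier = spec, scheme = scheme, accuracy = overall_accuracy(cm))
}
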