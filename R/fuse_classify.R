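#' Subselect feature-matrix columns by an mRMR selection
#'
#' Columns are reordered to the selection order; rows are untouched and
#' provenance-tagged feature names are preserved.
#'
#' @param fm a [feature_matrix()].
#' @param selection a `urised_selection` or an integer vector of unique
#'   1-based column indices.
#' @return A [feature_matrix()] with `length(selection)` columns.
#' @export
subselect <- function(fm, selection) {
  idx <- if (inherits(selection, "urised_selection")) selection$selected else as.integer(selection)
  if (anyDuplicated(idx)) stop("duplicate feature index in selection")
  if (length(idx) && (min(idx) < 1 || max(idx) > ncol(fm$values))) {
    stop("selection index out of range 1..", ncol(fm$values))
  }
  feature_matrix(fm$values[, idx, drop = FALSE], fm$sample_ids, fm$labels,
                 fm$feature_names[idx])
}

#' Fuse two feature blocks by horizontal concatenation
#'
#' Both blocks must describe the same samples in the same order; the fused
#' matrix keeps each block's provenance tags.
#'
#' @param block_a,block_b [feature_matrix()] objects over identical samples.
#' @return A [feature_matrix()] with `ncol(a) + ncol(b)` columns.
#' @export
fuse <- function(block_a, block_b) {
  mism <- which(block_a$sample_ids != block_b$sample_ids)
  if (length(mism)) {
    stop(sprintf("sample_id mismatch at row %d: '%s' vs '%s'",
                 mism[1], block_a$sample_ids[mism[1]], block_b$sample_ids[mism[1]]))
  }
  if (!identical(block_a$labels, block_b$labels)) {
    stop("label mismatch between blocks")
  }
  feature_matrix(cbind(block_a$values, block_b$values),
                 block_a$sample_ids, block_a$labels,
                 c(block_a$feature_names, block_b$feature_names))
}

#' Classifier specification
#'
#' Defaults follow the common point-and-click defaults of the six-classifier
#' family: `fine_tree` = decision tree (Gini, up to 100 splits);
#' `linear_discriminant` = pooled-covariance LDA with a 1e-6 ridge on the
#' covariance diagonal; `gaussian_naive_bayes` = per-class Gaussian with a
#' 1e-9 variance floor; `svm` = linear kernel, C = 1, one-vs-one;
#' `knn` = k = 5, Euclidean; `ensemble_bagged_trees` = 30 bagged trees.
#' Inputs are standardized (train-fold mean/sd) for the distance- and
#' margin-based kinds (svm, knn) and for the covariance-based kinds
#' (linear_discriminant, gaussian_naive_bayes).
#'
#' @param kind one of `fine_tree`, `linear_discriminant`,
#'   `gaussian_naive_bayes`, `svm`, `knn`, `ensemble_bagged_trees`.
#' @param hyperparams named list overriding the kind's documented defaults;
#'   unknown keys are an error.
#' @param seed integer seed for any stochastic component (bootstrap, ties).
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(kind = c("fine_tree", "linear_discriminant",
                                     "gaussian_naive_bayes", "svm", "knn",
                                     "ensemble_bagged_trees"),
                            hyperparams = list(), seed = 0L) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    fine_tree = list(max_splits = 100L, cp = 0),
    linear_discriminant = list(ridge = 1e-6),
    gaussian_naive_bayes = list(var_floor = 1e-9),
    svm = list(cost = 1),
    knn = list(k = 5L),
    ensemble_bagged_trees = list(n_trees = 30L))
  unknown <- setdiff(names(hyperparams), names(defaults))
  if (length(unknown)) {
    stop("unknown hyperparameters for ", kind, ": ", paste(unknown, collapse = ", "))
  }
  defaults[names(hyperparams)] <- hyperparams
  structure(list(kind = kind, hyperparams = defaults, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Evaluation scheme
#'
#' @param mode `"kfold_cv"` (default; pooled out-of-fold confusion matrix
#'   spanning every sample) or `"holdout"`.
#' @param train_fraction holdout train fraction.
#' @param folds number of CV folds.
#' @param stratified preserve class proportions across folds/split.
#' @param seed integer seed for fold assignment / the split.
#' @return An `eval_scheme` list.
#' @export
eval_scheme <- function(mode = c("kfold_cv", "holdout"), train_fraction = 0.8,
                        folds = 5L, stratified = TRUE, seed = 0L) {
  mode <- match.arg(mode)
  if (mode == "holdout" && (train_fraction <= 0 || train_fraction >= 1)) {
    stop("holdout needs 0 < train_fraction < 1")
  }
  if (mode == "kfold_cv" && folds < 2) stop("kfold_cv needs folds >= 2")
  structure(list(mode = mode, train_fraction = train_fraction,
                 folds = as.integer(folds), stratified = stratified,
                 seed = as.integer(seed)),
            class = "eval_scheme")
}

#' Train and evaluate one classifier
#'
#' Holdout mode returns the confusion matrix over the test fold; k-fold CV
#' returns the pooled out-of-fold confusion matrix spanning all samples,
#' together with per-fold matrices. Standardization statistics are fit on the
#' training portion only. Deterministic given the spec and scheme seeds.
#'
#' @param fm a [feature_matrix()].
#' @param classifier a [classifier_spec()].
#' @param scheme an [eval_scheme()].
#' @return List with `confusion` (K x K count matrix, rows = true class),
#'   `fold_confusions` (CV only), `classifier`, `scheme`, `accuracy` (%).
#' @export
train_eval <- function(fm, classifier = classifier_spec("svm"),
                       scheme = eval_scheme()) {
  X <- fm$values
  classes <- sort(unique(fm$labels))
  if (length(classes) < 2) stop("train_eval needs at least 2 classes")
  if (any(!is.finite(X))) stop("non-finite feature values")
  y <- factor(fm$labels, levels = classes)

  folds <- make_folds(fm, scheme)
  preds <- character(nrow(X))
  truth <- character(nrow(X))
  eval_rows <- integer(0)
  fold_confusions <- list()
  for (fi in seq_along(folds)) {
    fold <- folds[[fi]]
    fit_seed <- classifier$seed + 1000L * fi
    p <- with_seed(fit_seed,
                   fit_predict(classifier, X[fold$train, , drop = FALSE],
                               y[fold$train], X[fold$test, , drop = FALSE]))
    preds[fold$test] <- as.character(p)
    truth[fold$test] <- as.character(y[fold$test])
    eval_rows <- c(eval_rows, fold$test)
    fold_confusions[[fi]] <- confusion_from_labels(as.character(y[fold$test]),
                                                   as.character(p), classes)
  }
  cm <- confusion_from_labels(truth[eval_rows], preds[eval_rows], classes)
  list(confusion = cm,
       fold_confusions = if (scheme$mode == "kfold_cv") fold_confusions else NULL,
       classifier = classifier, scheme = scheme,
       accuracy = overall_accuracy(cm))
}

# Row-index folds: one train/test pair (holdout) or k CV folds.
make_folds <- function(fm, scheme) {
  n <- nrow(fm$values)
  labels <- fm$labels
  if (scheme$mode == "holdout") {
    recs <- lapply(seq_len(n), function(i) list(sample_id = fm$sample_ids[i], label = labels[i]))
    sp <- stratified_split(recs, scheme$train_fraction, scheme$seed)
    return(list(list(train = match(sp$train_ids, fm$sample_ids),
                     test = match(sp$test_ids, fm$sample_ids))))
  }
  k <- scheme$folds
  small <- names(which(table(labels) < k))
  if (length(small)) {
    stop("classes smaller than the fold count: ", paste(small, collapse = ", "))
  }
  assignment <- integer(n)
  if (scheme$stratified) {
    for (cls in sort(unique(labels))) {
      idx <- which(labels == cls)
      idx <- idx[order(fm$sample_ids[idx])]
      perm <- with_seed(scheme$seed + strtoi(substr(digest_hex(cls), 1, 6), 16L),
                        sample(idx))
      assignment[perm] <- rep_len(seq_len(k), length(perm))
    }
  } else {
    perm <- with_seed(scheme$seed, sample.int(n))
    assignment[perm] <- rep_len(seq_len(k), n)
  }
  lapply(seq_len(k), function(fi) {
    list(train = which(assignment != fi), test = which(assignment == fi))
  })
}

standardize_pair <- function(Xtr, Xte) {
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2, sd)
  sdv[sdv == 0] <- 1
  list(train = sweep(sweep(Xtr, 2, mu), 2, sdv, "/"),
       test = sweep(sweep(Xte, 2, mu), 2, sdv, "/"))
}

fit_predict <- function(spec, Xtr, ytr, Xte) {
  hp <- spec$hyperparams
  switch(spec$kind,
    fine_tree = {
      df <- as.data.frame(Xtr)
      names(df) <- sprintf("x%d", seq_len(ncol(Xtr)))
      df$.y <- ytr
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          control = rpart::rpart.control(
                            cp = hp$cp, xval = 0, maxsurrogate = 0,
                            maxdepth = 30, minsplit = 10,
                            maxcompete = 0))
      nd <- as.data.frame(Xte)
      names(nd) <- sprintf("x%d", seq_len(ncol(Xte)))
      factor(predict(fit, nd, type = "class"), levels = levels(ytr))
    },
    linear_discriminant = {
      z <- standardize_pair(Xtr, Xte)
      fit <- fit_rlda(z$train, ytr, ridge = hp$ridge)
      predict_rlda(fit, z$test)
    },
    gaussian_naive_bayes = {
      z <- standardize_pair(Xtr, Xte)
      colnames(z$train) <- colnames(z$test) <- sprintf("x%d", seq_len(ncol(Xtr)))
      fit <- e1071::naiveBayes(z$train, ytr)
      floor_sd <- sqrt(hp$var_floor)
      fit$tables <- lapply(fit$tables, function(tb) {
        tb[, 2] <- pmax(tb[, 2], floor_sd)
        tb
      })
      predict(fit, z$test, type = "class")
    },
    svm = {
      z <- standardize_pair(Xtr, Xte)
      fit <- e1071::svm(z$train, ytr, kernel = "linear", cost = hp$cost,
                        scale = FALSE)
      predict(fit, z$test)
    },
    knn = {
      z <- standardize_pair(Xtr, Xte)
      class::knn(z$train, z$test, ytr, k = hp$k)
    },
    ensemble_bagged_trees = {
      fit <- randomForest::randomForest(Xtr, ytr, ntree = hp$n_trees,
                                        mtry = ncol(Xtr))
      predict(fit, Xte)
    })
}

# Pooled-covariance linear discriminant with a ridge on the covariance
# diagonal; class priors are the training proportions.
fit_rlda <- function(X, y, ridge = 1e-6) {
  classes <- levels(y)
  mus <- t(vapply(classes, function(cl) colMeans(X[y == cl, , drop = FALSE]),
                  numeric(ncol(X))))
  Xc <- X - mus[as.integer(y), , drop = FALSE]
  S <- crossprod(Xc) / max(nrow(X) - length(classes), 1)
  diag(S) <- diag(S) + ridge
  Sinv_mu <- solve(S, t(mus))                   # p x K
  const <- -0.5 * colSums(t(mus) * Sinv_mu) + log(tabulate(y) / length(y))
  list(classes = classes, Sinv_mu = Sinv_mu, const = const)
}

predict_rlda <- function(fit, X) {
  scores <- X %*% fit$Sinv_mu + matrix(fit$const, nrow(X), length(fit$classes),
                                       byrow = TRUE)
  factor(fit$classes[max.col(scores, ties.method = "first")],
         levels = fit$classes)
}
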