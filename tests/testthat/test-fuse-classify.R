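test_that("subselect reorders columns and enforces the selection invariants", {
  fm <- make_gaussian_fm(10, p = 6, seed = 1)
  idx <- c(5L, 2L, 6L)
  sub <- subselect(fm, idx)
  expect_equal(dim(sub$values), c(20, 3))
  expect_identical(sub$feature_names, fm$feature_names[idx])
  expect_equal(unname(sub$values), unname(fm$values[, idx]))
  expect_identical(subselect(fm, seq_len(6))$values, fm$values)
  expect_error(subselect(fm, c(1L, 1L)), "duplicate")
  expect_error(subselect(fm, c(1L, 9L)), "out of range")
})

test_that("fusion concatenates aligned blocks and rejects misaligned ones", {
  a <- make_gaussian_fm(10, p = 4, seed = 2)
  b <- feature_matrix(matrix(rnorm(20 * 3), 20, 3), a$sample_ids, a$labels,
                      c("g1", "g2", "g3"))
  fused <- fuse(a, b)
  expect_equal(ncol(fused$values), 7)
  expect_identical(fused$feature_names, c(a$feature_names, b$feature_names))
  # empty block is an identity
  empty <- feature_matrix(matrix(numeric(0), 20, 0), a$sample_ids, a$labels, character(0))
  expect_identical(fuse(a, empty)$values, a$values)
  # shuffled rows are a fatal alignment error naming the first offender
  shuffled <- feature_matrix(b$values[20:1, ], rev(b$sample_ids), rev(b$labels),
                             b$feature_names)
  expect_error(fuse(a, shuffled), "row 1")
})

test_that("well-separated classes are classified perfectly by every kind", {
  fm <- make_gaussian_fm(100, n_classes = 2, p = 20, n_inf = 5, d = 6, seed = 0)
  for (kind in c("fine_tree", "linear_discriminant", "gaussian_naive_bayes",
                 "svm", "knn", "ensemble_bagged_trees")) {
    res <- train_eval(fm, classifier_spec(kind, seed = 0),
                      eval_scheme("kfold_cv", folds = 5, seed = 0))
    expect_equal(sum(res$confusion), 200)       # count conservation, all samples
    expect_gte(res$accuracy, 99, label = kind)
  }
})

test_that("permuted labels fall to chance under cross-validation", {
  for (seed in 1:2) {
    set.seed(seed)
    n <- 240
    y <- sample(rep(LETTERS[1:8], each = n / 8))
    X <- matrix(rnorm(n * 30), n, 30)
    fm <- feature_matrix(X, sprintf("s%03d", 1:n), y)
    res <- train_eval(fm, classifier_spec("svm"), eval_scheme("kfold_cv", folds = 5, seed = seed))
    se <- 100 * sqrt(0.125 * 0.875 / n)
    expect_lt(abs(res$accuracy - 12.5), 3 * se + 1e-9)
  }
})

test_that("holdout evaluates only the test fold and conserves counts", {
  fm <- make_gaussian_fm(50, n_classes = 2, seed = 1)
  res <- train_eval(fm, classifier_spec("svm"),
                    eval_scheme("holdout", train_fraction = 0.8, seed = 2))
  expect_equal(sum(res$confusion), 20)
  expect_null(res$fold_confusions)
})

test_that("evaluation is deterministic and tolerates fused column permutations", {
  fm <- make_gaussian_fm(40, n_classes = 3, p = 12, d = 4, seed = 5)
  r1 <- train_eval(fm, classifier_spec("ensemble_bagged_trees", seed = 7),
                   eval_scheme("kfold_cv", folds = 4, seed = 3))
  r2 <- train_eval(fm, classifier_spec("ensemble_bagged_trees", seed = 7),
                   eval_scheme("kfold_cv", folds = 4, seed = 3))
  expect_identical(r1$confusion, r2$confusion)
  perm <- sample(ncol(fm$values))
  fmp <- feature_matrix(fm$values[, perm], fm$sample_ids, fm$labels,
                        fm$feature_names[perm])
  for (kind in c("gaussian_naive_bayes", "knn", "linear_discriminant")) {
    a <- train_eval(fm, classifier_spec(kind, seed = 1), eval_scheme("kfold_cv", folds = 4, seed = 3))
    b <- train_eval(fmp, classifier_spec(kind, seed = 1), eval_scheme("kfold_cv", folds = 4, seed = 3))
    expect_identical(a$confusion, b$confusion, label = kind)
  }
})

test_that("invalid evaluation requests fail fatally", {
  fm <- make_gaussian_fm(3, n_classes = 2, seed = 1)
  expect_error(train_eval(fm, classifier_spec("svm"), eval_scheme("kfold_cv", folds = 5)),
               "smaller than the fold count")
  one <- feature_matrix(fm$values, fm$sample_ids, rep("a", 6))
  expect_error(train_eval(one, classifier_spec("svm")), "2 classes")
  expect_error(classifier_spec("svm", hyperparams = list(gamma = 2)), "unknown")
  expect_error(classifier_spec("boosted"))
})
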