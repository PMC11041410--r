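# Small separable/noise fixtures shared across detector tests.
make_feature_frame <- function(X) {
  colnames(X) <- pause_feature_names()
  as.data.frame(X)
}

separable_data <- function(n_groups = 20, per_group = 3, gap = 10, seed = 8) {
  withr::with_seed(seed, {
    n <- n_groups * per_group
    labels <- rep(rep(c(0L, 1L), length.out = n_groups), each = per_group)
    X <- matrix(stats::rnorm(n * 5), n, 5)
    X[labels == 1L, ] <- X[labels == 1L, ] + gap
    list(features = make_feature_frame(X), labels = labels,
         groups = rep(sprintf("g%02d", seq_len(n_groups)), each = per_group))
  })
}

test_that("groups never straddle folds and symmetric cases balance exactly", {
  labels <- rep(c(0, 1), 10)                 # 10 groups, 2 recordings each
  groups <- rep(sprintf("g%02d", 1:10), each = 2)
  folds <- stratified_group_kfold(rep(c(0, 1), 10), groups, k = 5, seed = 3)
  expect_equal(sort(unique(folds)), 1:5)
  per_fold <- table(folds[seq(1, 20, 2)])
  expect_true(all(per_fold == 2))            # two groups per fold
  for (g in unique(groups))
    expect_equal(length(unique(folds[groups == g])), 1)
  # class ratio identical across folds in the symmetric case
  ratios <- tapply(rep(c(0, 1), 10), folds, mean)
  expect_true(all(ratios == ratios[1]))
})

test_that("fold assignment is group-atomic, order-invariant and near-stratified", {
  withr::with_seed(41, {
    n_groups <- 17
    sizes <- sample(1:6, n_groups, replace = TRUE)
    groups <- rep(sprintf("g%02d", seq_len(n_groups)), times = sizes)
    labels <- stats::rbinom(length(groups), 1, 0.6)
  })
  folds <- stratified_group_kfold(labels, groups, k = 5, seed = 7)
  for (g in unique(groups))
    expect_equal(length(unique(folds[groups == g])), 1)
  perm <- withr::with_seed(2, sample(seq_along(groups)))
  folds_perm <- stratified_group_kfold(labels[perm], groups[perm], k = 5,
                                       seed = 7)
  expect_equal(folds_perm, folds[perm])
  expect_error(stratified_group_kfold(c(0, 1, 0), c("a", "a", "b"), k = 5),
               "fewer distinct groups")
})

test_that("the training cohort yields five class-balanced participant folds", {
  meta <- reference_cohort()
  cfg <- default_split_config(meta)
  tr <- assign_split(meta, cfg) == "train"
  folds <- stratified_group_kfold(meta$label[tr], meta$group_id[tr], k = 5,
                                  seed = 1)
  counts <- table(folds, meta$label[tr])
  global_ratio <- mean(meta$label[tr])
  for (f in 1:5) {
    n_f <- sum(counts[f, ])
    expect_lte(abs(counts[f, "1"] - global_ratio * n_f), 2)
  }
})

test_that("balanced accuracy follows the sensitivity/specificity arithmetic", {
  expect_equal(balanced_accuracy(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(balanced_accuracy(c(0, 0, 1, 1), c(1, 1, 1, 1)), 0.5)
  # printed-count block: 25/26 authentic and 17/21 fakes correct
  y_true <- c(rep(0, 26), rep(1, 21))
  y_pred <- c(rep(0, 25), 1, rep(1, 17), rep(0, 4))
  expect_equal(balanced_accuracy(y_true, y_pred), (25 / 26 + 17 / 21) / 2)
  expect_equal(round(balanced_accuracy(y_true, y_pred), 4), 0.8855)
  expect_error(balanced_accuracy(c(1, 1), c(1, 0)), "single class")
})

test_that("all five families solve a widely separated problem perfectly", {
  d <- separable_data()
  cv <- suppressWarnings(
    cross_validate_models(d$features, d$labels, d$groups, seed = 5))
  expect_setequal(cv$summary$family, model_families())
  expect_true(all(cv$summary$balanced_accuracy_mean > 0.999))
})

test_that("random labels give chance-level cross-validated accuracy", {
  withr::with_seed(13, {
    n <- 90
    X <- make_feature_frame(matrix(stats::rnorm(n * 5), n, 5))
    labels <- stats::rbinom(n, 1, 0.5)
    groups <- rep(sprintf("g%02d", 1:30), each = 3)
  })
  grids <- list(DT = data.frame(maxdepth = 3),
                LR = data.frame(lambda = 1))
  cv <- suppressWarnings(
    cross_validate_models(X, labels, groups, grids = grids, seed = 11))
  # within 3 SD of 0.5 under the null
  for (i in seq_len(nrow(cv$summary))) {
    sdv <- max(cv$summary$balanced_accuracy_sd[i] / sqrt(5), 0.02)
    expect_lt(abs(cv$summary$balanced_accuracy_mean[i] - 0.5), 3 * sdv + 0.1)
  }
})

test_that("cross-validation is deterministic for a fixed seed", {
  d <- separable_data(n_groups = 12, gap = 2, seed = 17)
  grids <- list(RF = data.frame(ntree = 100, maxdepth = NA),
                ADA = data.frame(n_estimators = 25, learning_rate = 1))
  cv1 <- cross_validate_models(d$features, d$labels, d$groups, grids, seed = 4)
  cv2 <- cross_validate_models(d$features, d$labels, d$groups, grids, seed = 4)
  expect_equal(cv1$summary, cv2$summary)
  expect_equal(cv1$folds, cv2$folds)
})

test_that("an unconstrained decision tree memorizes its training data", {
  d <- separable_data(n_groups = 10, gap = 0.5, seed = 23)
  model <- fit_final_model(d$features, d$labels, "DT", list(maxdepth = 30))
  expect_equal(mean(predict(model, d$features) == d$labels), 1)
})

test_that("detector scores are monotone with the predicted class and separate perfectly when separable", {
  d <- separable_data(seed = 31)
  for (fam in model_families()) {
    params <- switch(fam, RF = list(ntree = 100, maxdepth = NA),
                     DT = list(maxdepth = 4), LR = list(lambda = 0.1),
                     SVM = list(cost = 1, gamma = NA),
                     ADA = list(n_estimators = 25, learning_rate = 1))
    model <- fit_final_model(d$features, d$labels, fam, params, seed = 2)
    pred <- predict(model, d$features)
    sc <- detector_score(model, d$features)
    if (length(unique(pred)) == 2L)
      expect_gte(mean(sc[pred == 1L]), mean(sc[pred == 0L]))
    expect_equal(auc_rank(sc, d$labels), 1, info = fam)
  }
})

test_that("wrong feature arity is a usage error", {
  d <- separable_data(n_groups = 8, seed = 37)
  model <- fit_final_model(d$features, d$labels, "DT", list(maxdepth = 3))
  expect_error(predict(model, d$features[, 1:3]), "five pause features")
})
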