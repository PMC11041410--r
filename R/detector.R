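#' Default hyperparameter grids for the five model families
#'
#' Small grids suited to a 5-feature space: random forest over tree count and
#' depth, decision tree over depth, ridge logistic regression over penalty
#' strength, RBF support vector machine over cost and kernel width (`NA` =
#' scale heuristic), and AdaBoost stumps over rounds and learning rate. Users
#' can substitute their own grids (a named list of data frames) in
#' [cross_validate_models()].
#'
#' @return Named list of data frames, one per family.
#' @export
default_model_grids <- function() {
  list(
    RF = expand.grid(ntree = c(100, 300), maxdepth = c(3, 5, NA)),
    DT = data.frame(maxdepth = 2:8),
    LR = data.frame(lambda = c(0.01, 0.1, 1, 10)),
    SVM = expand.grid(cost = c(0.1, 1, 10), gamma = c(NA, 0.1, 1)),
    ADA = expand.grid(n_estimators = c(25, 50, 100, 200),
                      learning_rate = c(0.5, 1.0))
  )
}

feature_matrix <- function(features) {
  feats <- pause_feature_names()
  if (!all(feats %in% names(features)))
    stop("feature table must contain the five pause features")
  as.matrix(features[, feats, drop = FALSE])
}

#' Cross-validate the five model families with grid search
#'
#' Evaluates every grid point of every family under one fixed participant-
#' grouped stratified 5-fold assignment, selecting each family's best
#' configuration by highest mean balanced accuracy across folds (ties broken
#' by grid order). A validation fold containing a single class is skipped for
#' that configuration with a warning.
#'
#' @param features feature table containing the five pause features.
#' @param labels binary labels (0 authentic, 1 fake).
#' @param groups group (participant) ID per recording.
#' @param grids named list of per-family grids; see [default_model_grids()].
#' @param k number of folds (default 5).
#' @param seed master seed for fold assignment and stochastic learners.
#' @return Object of class `pause_cv`: list with `summary` (one row per
#'   family, sorted by mean balanced accuracy), `best_params` (named list),
#'   `folds` (the shared fold assignment), and `per_fold` (balanced accuracy
#'   per fold for each family's selected configuration).
#' @export
cross_validate_models <- function(features, labels, groups,
                                  grids = default_model_grids(), k = 5,
                                  seed = 1) {
  X <- feature_matrix(features)
  y <- as.integer(labels)
  stopifnot(nrow(X) == length(y), length(y) == length(groups))
  if (length(grids) == 0L || any(!vapply(grids, nrow, integer(1)) > 0))
    stop("grids must be non-empty")
  folds <- stratified_group_kfold(y, groups, k = k, seed = seed)
  metric_names <- c("sensitivity", "specificity", "balanced_accuracy",
                    "precision", "f1")
  summary_rows <- list()
  best_params <- list()
  per_fold <- list()
  for (family in names(grids)) {
    grid <- grids[[family]]
    best <- NULL
    for (gi in seq_len(nrow(grid))) {
      params <- as.list(grid[gi, , drop = FALSE])
      fold_vals <- matrix(NA_real_, nrow = k, ncol = length(metric_names),
                          dimnames = list(NULL, metric_names))
      for (f in seq_len(k)) {
        tr <- folds != f
        te <- !tr
        if (length(unique(y[te])) < 2L) {
          warning(sprintf("fold %d has a single class; skipped for %s", f,
                          family))
          next
        }
        obj <- withr::with_seed(seed + f, fit_learner(family, X[tr, , drop = FALSE],
                                                      y[tr], params))
        pred <- predict_learner(obj, X[te, , drop = FALSE])
        fold_vals[f, ] <- fold_metrics(y[te], pred)
      }
      mean_ba <- mean(fold_vals[, "balanced_accuracy"], na.rm = TRUE)
      if (is.null(best) || mean_ba > best$mean_ba + 1e-12) {
        best <- list(mean_ba = mean_ba, params = params,
                     fold_vals = fold_vals)
      }
    }
    mu <- colMeans(best$fold_vals, na.rm = TRUE)
    sdv <- apply(best$fold_vals, 2, stats::sd, na.rm = TRUE)
    summary_rows[[family]] <- data.frame(
      family = family,
      balanced_accuracy_mean = mu[["balanced_accuracy"]],
      balanced_accuracy_sd = sdv[["balanced_accuracy"]],
      sensitivity_mean = mu[["sensitivity"]],
      sensitivity_sd = sdv[["sensitivity"]],
      specificity_mean = mu[["specificity"]],
      specificity_sd = sdv[["specificity"]],
      precision_mean = mu[["precision"]], precision_sd = sdv[["precision"]],
      f1_mean = mu[["f1"]], f1_sd = sdv[["f1"]],
      params = paste(names(best$params),
                     vapply(best$params, function(v) format(v), character(1)),
                     sep = "=", collapse = ", ")
    )
    best_params[[family]] <- best$params
    per_fold[[family]] <- best$fold_vals[, "balanced_accuracy"]
  }
  summary <- do.call(rbind, summary_rows)
  summary <- summary[order(-summary$balanced_accuracy_mean), ]
  row.names(summary) <- NULL
  structure(list(summary = summary, best_params = best_params, folds = folds,
                 per_fold = per_fold, seed = seed, k = k),
            class = "pause_cv")
}

#' @export
print.pause_cv <- function(x, ...) {
  cat(sprintf("Grouped stratified %d-fold cross-validation (seed %d)\n", x$k,
              x$seed))
  df <- x$summary
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-3s balanced accuracy %.2f (SD %.2f)  [%s]\n",
                df$family[i], df$balanced_accuracy_mean[i],
                df$balanced_accuracy_sd[i], df$params[i]))
  }
  invisible(x)
}

#' Fit the final detector on all training recordings
#'
#' Refits the selected family with its tuned hyperparameters on the full
#' training set.
#'
#' @param features training feature table.
#' @param labels binary labels.
#' @param family model family (usually the cross-validation winner).
#' @param params named list of hyperparameters for that family.
#' @param seed seed for stochastic learners.
#' @return Object of class `pause_detector`.
#' @export
fit_final_model <- function(features, labels, family, params, seed = 1) {
  X <- feature_matrix(features)
  obj <- withr::with_seed(seed, fit_learner(family, X, as.integer(labels), params))
  structure(list(learner = obj, family = family, params = params,
                 feature_names = pause_feature_names()),
            class = "pause_detector")
}

#' Predict authenticity labels
#' @param object a `pause_detector`.
#' @param features feature table with the five pause features.
#' @param ... unused.
#' @return Integer labels (0 authentic, 1 fake).
#' @export
predict.pause_detector <- function(object, features, ...) {
  predict_learner(object$learner, feature_matrix(features))
}

#' Continuous fake score of the final detector
#'
#' Higher scores mean more fake-like; used for ROC/AUC.
#'
#' @param object a `pause_detector`.
#' @param features feature table.
#' @return Numeric scores.
#' @export
detector_score <- function(object, features) {
  stopifnot(inherits(object, "pause_detector"))
  score_learner(object$learner, feature_matrix(features))
}
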