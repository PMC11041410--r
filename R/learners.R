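# Learner backends for the five model families. Each fit returns an object
# with enough state to predict a binary label and a continuous fake score on
# new feature matrices (rows = recordings, columns = pause features).
# Features are standardized with training-fold mean/SD for LR and SVM and fed
# raw to the tree-based families.

standardizer <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(center = mu, scale = sdv)
}

apply_standardizer <- function(std, X) {
  scale(X, center = std$center, scale = std$scale)
}

#' Model families available to the detector
#' @return Character vector: ADA, SVM, RF, LR, DT.
#' @export
model_families <- function() c("ADA", "SVM", "RF", "LR", "DT")

fit_learner <- function(family, X, y, params) {
  X <- as.matrix(X)
  y <- as.integer(y)
  obj <- switch(family,
    RF = {
      maxnodes <- if (is.null(params$maxdepth) || is.na(params$maxdepth))
        NULL else 2^params$maxdepth
      list(fit = randomForest::randomForest(
        x = X, y = factor(y, levels = c(0, 1)),
        ntree = params$ntree, maxnodes = maxnodes))
    },
    DT = {
      d <- data.frame(X, .y = factor(y, levels = c(0, 1)))
      list(fit = rpart::rpart(
        .y ~ ., data = d, method = "class",
        control = rpart::rpart.control(maxdepth = params$maxdepth, cp = 0,
                                       minsplit = 4, xval = 0)))
    },
    LR = {
      std <- standardizer(X)
      Xs <- apply_standardizer(std, X)
      list(std = std, lambda = params$lambda,
           fit = glmnet::glmnet(Xs, factor(y, levels = c(0, 1)),
                                family = "binomial", alpha = 0,
                                lambda = params$lambda, standardize = FALSE))
    },
    SVM = {
      std <- standardizer(X)
      Xs <- apply_standardizer(std, X)
      gamma <- if (is.null(params$gamma) || is.na(params$gamma)) {
        v <- stats::var(as.vector(Xs))
        1 / (ncol(Xs) * max(v, 1e-12)) # scale heuristic
      } else params$gamma
      fit <- e1071::svm(Xs, factor(y, levels = c(0, 1)), kernel = "radial",
                        cost = params$cost, gamma = gamma, scale = FALSE)
      list(std = std, fit = fit)
    },
    ADA = {
      list(fit = fit_adaboost_stumps(X, y, n_estimators = params$n_estimators,
                                     learning_rate = params$learning_rate))
    },
    stop(sprintf("unknown model family: %s", family))
  )
  obj$family <- family
  obj$feature_names <- colnames(X)
  class(obj) <- "pause_learner"
  obj
}

# Continuous fake score (higher = more fake-like) and thresholded label.
score_learner <- function(obj, X) {
  X <- as.matrix(X)
  switch(obj$family,
    RF = unname(stats::predict(obj$fit, X, type = "prob")[, "1"]),
    DT = unname(stats::predict(obj$fit, data.frame(X), type = "prob")[, "1"]),
    LR = as.numeric(stats::predict(obj$fit, apply_standardizer(obj$std, X),
                                   s = obj$lambda, type = "response")),
    SVM = {
      pr <- stats::predict(obj$fit, apply_standardizer(obj$std, X),
                           decision.values = TRUE)
      dv <- as.numeric(attr(pr, "decision.values"))
      # orient the decision value so larger means class "1"
      if (grepl("^0/1", colnames(attr(pr, "decision.values"))[1])) -dv else dv
    },
    ADA = predict_adaboost_stumps(obj$fit, X)
  )
}

predict_learner <- function(obj, X) {
  s <- score_learner(obj, X)
  thr <- switch(obj$family, RF = 0.5, DT = 0.5, LR = 0.5, SVM = 0, ADA = 0)
  as.integer(s > thr)
}

# Discrete (two-class SAMME) AdaBoost over depth-1 rpart stumps. The weak
# learner is refit on reweighted data each round; rounds stop early if a
# stump cannot beat chance on the weighted sample.
fit_adaboost_stumps <- function(X, y, n_estimators = 50, learning_rate = 1.0) {
  n <- nrow(X)
  d <- data.frame(X, .y = factor(y, levels = c(0, 1)))
  w <- rep(1 / n, n)
  stumps <- vector("list", n_estimators)
  alphas <- numeric(n_estimators)
  m_used <- 0L
  ctrl <- rpart::rpart.control(maxdepth = 1, cp = 0, minsplit = 2,
                               minbucket = 1, xval = 0)
  for (m in seq_len(n_estimators)) {
    fit <- rpart::rpart(.y ~ ., data = d, weights = w * n, method = "class",
                        control = ctrl)
    pred <- as.integer(as.character(stats::predict(fit, type = "class")))
    err <- sum(w[pred != y])
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- learning_rate * log((1 - err) / err)
    m_used <- m
    stumps[[m]] <- fit
    alphas[m] <- alpha
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
    if (err <= 1e-10) break
  }
  if (m_used == 0L) {
    # no stump beats chance: fall back to the majority class
    return(list(stumps = list(), alphas = numeric(0),
                fallback = as.integer(mean(y) >= 0.5)))
  }
  list(stumps = stumps[seq_len(m_used)], alphas = alphas[seq_len(m_used)],
       fallback = NULL)
}

# Weighted vote margin in [-1, 1]; positive = fake.
predict_adaboost_stumps <- function(model, X) {
  X <- data.frame(as.matrix(X))
  if (length(model$stumps) == 0L)
    return(rep(if (model$fallback == 1L) 1 else -1, nrow(X)))
  votes <- vapply(model$stumps, function(s) {
    as.integer(as.character(stats::predict(s, X, type = "class")))
  }, integer(nrow(X)))
  votes <- matrix(votes, nrow = nrow(X))
  as.numeric((votes * 2 - 1) %*% model$alphas) / sum(model$alphas)
}
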