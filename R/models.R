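# Model registry: ten classifier families mirrored by role -- four
# tree-based (flagged for importance/SHAP use), two linear, one kernel-based,
# one neural network, two ensembles. Each entry carries a small fixed
# hyperparameter grid; fits consume the session RNG, so callers seed per
# round for reproducibility. X is a numeric matrix with sanitized column
# names; y is an integer 0/1 vector.

fit_cart <- function(X, y, params) {
  df <- data.frame(.y = factor(y, levels = c(0, 1)), X, check.names = FALSE)
  rpart::rpart(.y ~ ., data = df, method = "class",
               cp = params$cp %||% 0.01,
               minsplit = 5, model = FALSE, y = FALSE)
}
predict_cart <- function(fit, X) {
  predict(fit, newdata = as.data.frame(X), type = "prob")[, "1"]
}

fit_rf <- function(X, y, params) {
  randomForest::randomForest(
    x = X, y = factor(y, levels = c(0, 1)),
    ntree = params$ntree %||% 100,
    mtry = max(1, floor(sqrt(ncol(X))))
  )
}
fit_bagged <- function(X, y, params) {
  # bagging of unpruned trees = a forest without feature subsampling
  randomForest::randomForest(
    x = X, y = factor(y, levels = c(0, 1)),
    ntree = params$ntree %||% 100, mtry = ncol(X)
  )
}
predict_rf <- function(fit, X) {
  predict(fit, newdata = X, type = "prob")[, "1"]
}

fit_extratrees <- function(X, y, params) {
  df <- data.frame(.y = factor(y, levels = c(0, 1)), X, check.names = FALSE)
  ranger::ranger(
    dependent.variable.name = ".y", data = df,
    num.trees = params$num_trees %||% 100,
    splitrule = "extratrees", probability = TRUE,
    importance = "impurity", num.threads = 1,
    seed = sample.int(.Machine$integer.max, 1)
  )
}
predict_extratrees <- function(fit, X) {
  predict(fit, data = as.data.frame(X), num.threads = 1)$predictions[, "1"]
}

fit_xgb <- function(X, y, params) {
  xgboost::xgb.train(
    params = list(
      objective = params$objective %||% "binary:logistic",
      max_depth = params$max_depth %||% 3,
      eta = params$eta %||% 0.3,
      base_score = 0.5, # fixed so the margin intercept is known exactly
      nthread = 1
    ),
    data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
    nrounds = params$nrounds %||% 30,
    verbose = 0
  )
}
predict_xgb <- function(fit, X) {
  as.numeric(predict(fit, xgboost::xgb.DMatrix(X, nthread = 1)))
}

fit_glmnet <- function(alpha) {
  function(X, y, params) {
    glmnet::glmnet(X, y, family = "binomial", alpha = alpha,
                   lambda = params$lambda %||% 0.05)
  }
}
predict_glmnet <- function(fit, X) {
  as.numeric(predict(fit, X, type = "response"))
}

fit_svm <- function(X, y, params) {
  e1071::svm(x = X, y = factor(y, levels = c(0, 1)),
             kernel = "radial", cost = params$cost %||% 1,
             probability = TRUE)
}
predict_svm <- function(fit, X) {
  p <- predict(fit, X, probability = TRUE)
  attr(p, "probabilities")[, "1"]
}

fit_mlp <- function(X, y, params) {
  nnet::nnet(x = X, y = y, size = params$size %||% 3,
             decay = params$decay %||% 0.5, maxit = 200,
             entropy = TRUE, trace = FALSE, MaxNWts = 5000)
}
predict_mlp <- function(fit, X) {
  as.numeric(predict(fit, X))
}

fit_voting <- function(X, y, params) {
  # soft-voting ensemble over three heterogeneous base learners
  list(
    ridge = fit_glmnet(0)(X, y, list(lambda = 0.05)),
    cart = fit_cart(X, y, list(cp = 0.01)),
    svm = fit_svm(X, y, list(cost = 1))
  )
}
predict_voting <- function(fit, X) {
  (predict_glmnet(fit$ridge, X) + predict_cart(fit$cart, X) +
     predict_svm(fit$svm, X)) / 3
}

#' The ten-model classifier registry
#'
#' Ten classification model families used by the training harness: four
#' tree-based (CART, random forest, extremely randomized trees, gradient
#' boosting; these are the source of impurity importances and tree-SHAP
#' attributions), two linear (ridge- and lasso-regularized logistic
#' regression), one kernel-based (RBF support vector machine), one neural
#' network (single-hidden-layer perceptron), and two ensembles (bagged
#' trees, soft-voting over heterogeneous learners). Each entry has a small
#' fixed hyperparameter grid explored by cross-validation.
#'
#' @return A tibble with columns `model_id`, `role`, `tree_based`, and
#'   list-columns `fit`, `predict`, `grid`.
#' @export
model_registry <- function() {
  tibble(
    model_id = c("cart", "random_forest", "extra_trees", "gradient_boosting",
                 "logistic_ridge", "logistic_lasso", "svm_rbf", "mlp",
                 "bagged_trees", "soft_voting"),
    role = c("tree", "tree", "tree", "tree", "linear", "linear", "kernel",
             "neural", "ensemble", "ensemble"),
    tree_based = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE,
                   FALSE, FALSE),
    fit = list(fit_cart, fit_rf, fit_extratrees, fit_xgb,
               fit_glmnet(0), fit_glmnet(1), fit_svm, fit_mlp,
               fit_bagged, fit_voting),
    predict = list(predict_cart, predict_rf, predict_extratrees, predict_xgb,
                   predict_glmnet, predict_glmnet, predict_svm, predict_mlp,
                   predict_rf, predict_voting),
    grid = list(
      list(list(cp = 0.01), list(cp = 0.05)),
      list(list(ntree = 100)),
      list(list(num_trees = 100)),
      list(list(max_depth = 2), list(max_depth = 3)),
      list(list(lambda = 0.01), list(lambda = 0.1)),
      list(list(lambda = 0.005), list(lambda = 0.05)),
      list(list(cost = 1), list(cost = 10)),
      list(list(decay = 0.1), list(decay = 1)),
      list(list(ntree = 100)),
      list(list())
    )
  )
}

# per-model normalized impurity importance over sanitized feature names
model_importance <- function(model_id, fit, feature_names) {
  imp <- switch(model_id,
    cart = {
      v <- fit$variable.importance
      if (is.null(v)) setNames(numeric(0), character(0)) else v
    },
    random_forest = ,
    bagged_trees = setNames(randomForest::importance(fit)[, 1],
                            rownames(randomForest::importance(fit))),
    extra_trees = fit$variable.importance,
    gradient_boosting = {
      tab <- xgboost::xgb.importance(model = fit)
      setNames(tab$Gain, tab$Feature)
    },
    abort(paste0("no importance for model: ", model_id))
  )
  out <- setNames(numeric(length(feature_names)), feature_names)
  imp <- imp[names(imp) %in% feature_names]
  out[names(imp)] <- pmax(imp, 0)
  if (sum(out) > 0) out <- out / sum(out)
  out
}
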