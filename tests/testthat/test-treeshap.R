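# Brute-force Shapley oracle with the tree's own conditional expectation as
# the value function: v(S) routes features in S by the sample and averages
# the rest by cover weights. This is the exact quantity the polynomial
# TreeSHAP algorithm computes, evaluated by direct subset enumeration.
brute_shapley <- function(ensemble, x, n_features) {
  cond_exp <- function(tree, S) {
    rec <- function(node) {
      f <- tree$feature[node]
      if (is.na(f)) return(tree$value[node])
      if (f %in% S) {
        nxt <- if (cpprofiler:::tree_left(tree, node, x[f]))
          tree$yes[node] else tree$no[node]
        return(rec(nxt))
      }
      wl <- tree$cover[tree$yes[node]] / tree$cover[node]
      wl * rec(tree$yes[node]) + (1 - wl) * rec(tree$no[node])
    }
    rec(1L)
  }
  v <- function(S) {
    vals <- vapply(ensemble$trees, cond_exp, numeric(1), S = S)
    if (ensemble$combine == "average") mean(vals) else sum(vals)
  }
  phi <- numeric(n_features)
  feats <- seq_len(n_features)
  for (f in feats) {
    others <- setdiff(feats, f)
    for (k in 0:length(others)) {
      combos <- utils::combn(others, k, simplify = FALSE)
      if (k == 0) combos <- list(integer(0))
      w <- factorial(k) * factorial(n_features - k - 1) /
        factorial(n_features)
      for (S in combos) {
        phi[f] <- phi[f] + w * (v(c(S, f)) - v(S))
      }
    }
  }
  phi
}

make_xy <- function(n = 50, p = 4, seed = 1) {
  set.seed(seed)
  X <- matrix(runif(n * p), n, p,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("f%05d", 1:p)))
  y <- as.integer(X[, 1] + X[, 2] + stats::rnorm(n, 0, 0.3) > 1)
  list(X = X, y = y)
}

test_that("TreeSHAP matches brute-force Shapley for all four model types", {
  d <- make_xy()
  fitters <- list(
    cart = function() cpprofiler:::fit_cart(d$X, d$y, list(cp = 0.02)),
    random_forest = function() cpprofiler:::fit_rf(d$X, d$y,
                                                   list(ntree = 5)),
    extra_trees = function() cpprofiler:::fit_extratrees(d$X, d$y,
                                                         list(num_trees = 5)),
    gradient_boosting = function() cpprofiler:::fit_xgb(
      d$X, d$y, list(nrounds = 4, max_depth = 2,
                     objective = "reg:squarederror"))
  )
  for (model_id in names(fitters)) {
    set.seed(7)
    fit <- fitters[[model_id]]()
    ens <- extract_trees(model_id, fit, d$X, colnames(d$X))
    for (i in c(1, 13, 37)) {
      x <- d$X[i, ]
      if (isTRUE(ens$f32)) x <- cpprofiler:::as_float32(x)
      mine <- cpprofiler:::shap_tree(ens$trees[[1]], x, ncol(d$X))
      # single-tree check against enumeration
      single <- list(trees = ens$trees[1], combine = "average",
                     intercept = 0)
      expect_equal(mine, brute_shapley(single, x, ncol(d$X)),
                   tolerance = 1e-10,
                   label = paste(model_id, "tree shap, sample", i))
      # full-ensemble check
      ts <- tree_shap(ens, d$X[i, , drop = FALSE])
      expect_equal(as.numeric(ts$shap),
                   brute_shapley(ens, x, ncol(d$X)),
                   tolerance = 1e-10,
                   label = paste(model_id, "ensemble shap, sample", i))
    }
  }
})

test_that("additivity holds against each package's own predictions", {
  d <- make_xy(n = 60, p = 5, seed = 3)
  set.seed(11)
  checks <- list(
    cart = list(
      fit = cpprofiler:::fit_cart(d$X, d$y, list(cp = 0.01)),
      pred = cpprofiler:::predict_cart
    ),
    random_forest = list(
      fit = cpprofiler:::fit_rf(d$X, d$y, list(ntree = 30)),
      pred = cpprofiler:::predict_rf
    ),
    extra_trees = list(
      fit = cpprofiler:::fit_extratrees(d$X, d$y, list(num_trees = 30)),
      pred = cpprofiler:::predict_extratrees
    )
  )
  for (model_id in names(checks)) {
    ens <- extract_trees(model_id, checks[[model_id]]$fit, d$X,
                         colnames(d$X))
    ts <- tree_shap(ens, d$X)
    ref <- checks[[model_id]]$pred(checks[[model_id]]$fit, d$X)
    expect_lt(max(abs(ts$base + rowSums(ts$shap) - ref)), 1e-6)
  }
  # gradient boosting: additivity on the margin, and agreement with the
  # library's own exact tree-SHAP as an independent oracle
  fit <- cpprofiler:::fit_xgb(d$X, d$y,
                              list(nrounds = 15, max_depth = 3,
                                   objective = "reg:squarederror"))
  ens <- extract_trees("gradient_boosting", fit, d$X, colnames(d$X))
  ts <- tree_shap(ens, d$X)
  dm <- xgboost::xgb.DMatrix(d$X, nthread = 1)
  marg <- predict(fit, dm, outputmargin = TRUE)
  expect_lt(max(abs(ts$base + rowSums(ts$shap) - marg)), 1e-6)
  contrib <- predict(fit, dm, predcontrib = TRUE)
  expect_lt(max(abs(ts$shap - contrib[, seq_len(ncol(d$X))])), 1e-6)
})
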