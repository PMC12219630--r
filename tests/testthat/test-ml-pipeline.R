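test_that("the registry holds ten models in the stated roles", {
  reg <- model_registry()
  expect_equal(nrow(reg), 10)
  expect_equal(unname(table(reg$role)[c("tree", "linear", "kernel", "neural",
                                        "ensemble")]),
               c(4L, 2L, 1L, 1L, 2L), ignore_attr = TRUE)
  expect_equal(sum(reg$tree_based), 4)
  expect_true(all(reg$tree_based == (reg$role == "tree")))
})

test_that("the harness fits rounds x models final models, reproducibly", {
  fx <- small_cpp()
  reg <- model_registry()[c(1, 5), ] # cart + ridge: fast
  b <- monte_carlo_train(fx$res$matrix, fx$res$labels, registry = reg,
                         n_rounds = 3, top_k_grid = 10, seed_base = 99)
  tt <- tidy(b)
  expect_equal(nrow(tt), 3 * 2)

  b2 <- monte_carlo_train(fx$res$matrix, fx$res$labels, registry = reg,
                          n_rounds = 3, top_k_grid = 10, seed_base = 99)
  expect_equal(tidy(b2), tt)
  expect_identical(lapply(b2$rounds, `[[`, "test_ids"),
                   lapply(b$rounds, `[[`, "test_ids"))
})

test_that("training scores obey the out-of-fold discipline", {
  b <- small_bundle()
  scores <- suppressWarnings(predict_score(b, small_cpp()$res$matrix))
  n_models_per_round <- length(b$rounds[[1]]$fits)
  for (i in seq_len(nrow(scores))) {
    id <- scores$id[i]
    if (!id %in% b$labeled_ids) next
    rounds_out <- sum(vapply(b$rounds, function(rd) id %in% rd$test_ids,
                             logical(1)))
    expect_equal(scores$n_models[i], rounds_out * n_models_per_round)
  }
  # unlabeled proteins are scored by every model
  unl <- scores[!scores$id %in% b$labeled_ids, ]
  expect_true(all(unl$n_models ==
                    length(b$rounds) * n_models_per_round))
  expect_true(all(unl$score >= 0 & unl$score <= 1))
})

test_that("confidence classes follow the score cut-offs", {
  expect_equal(confidence_class(c(0.85, 0.8, 0.79, 0.5, 0.49, 0.21, 0.2, 0)),
               c("HC substrate", "HC substrate", "LC substrate",
                 "LC substrate", "LC non-substrate", "LC non-substrate",
                 "HC non-substrate", "HC non-substrate"))
  expect_error(confidence_class(1.2), "0, 1")
})

test_that("approach aggregation reports mean and n-1 standard deviation", {
  wide <- tibble::tibble(id = c("a", "b"), ap1 = c(0.8, 0.3),
                         ap2 = c(1.0, 0.3))
  agg <- aggregate_approaches(wide)
  expect_equal(agg$score[agg$id == "a"], 0.9)
  expect_equal(agg$sd[agg$id == "a"], stats::sd(c(0.8, 1.0)))
  expect_equal(agg$sd[agg$id == "b"], 0)
  expect_equal(agg$confidence, c("HC substrate", "LC non-substrate"))

  six <- tibble::tibble(
    id = "x",
    approach = paste0("ap", 1:6),
    score = c(0.9, 0.85, 0.8, 0.95, 0.7, 0.75)
  )
  agg6 <- aggregate_approaches(six)
  expect_equal(agg6$score, mean(six$score))
  expect_equal(agg6$sd, stats::sd(six$score))
})

test_that("tree importances are normalized and favor planted features", {
  b <- small_bundle()
  imp <- tree_feature_importance(b)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_true(all(imp$importance >= 0))
  # top importance lands on a planted-region feature
  fx <- small_cpp()
  top_feat <- fx$res$features[
    fx$res$features$feature_id == imp$feature_id[1], ]
  planted <- unlist(purrr::map2(fx$sim$truth$regions$start,
                                fx$sim$truth$regions$stop, seq))
  expect_true(any(top_feat$positions[[1]] %in% planted))
})

test_that("balanced accuracy combines sensitivity and specificity", {
  b <- small_bundle()
  ev <- evaluate_bundle(b)
  overall <- ev[ev$model_id == "overall", ]
  sens <- overall$tp / (overall$tp + overall$fn)
  spec <- overall$tn / (overall$tn + overall$fp)
  expect_equal(overall$balanced_accuracy, (sens + spec) / 2)
  # hand check of the formula on a fixed confusion
  expect_equal((9 / (9 + 1) + 8 / (8 + 2)) / 2, 0.85)

  rows <- c(1:10, 21:30) # ten positives, ten negatives
  lo <- evaluate_loocv(small_cpp()$res$matrix[rows, ],
                       small_cpp()$res$labels[rows],
                       model_id = "logistic_ridge")
  expect_equal(lo$tp + lo$fn + lo$tn + lo$fp, 20)
  expect_gte(lo$balanced_accuracy, 0.8) # planted signal, easy separation
})

test_that("the relevance score averages the five binary factors", {
  expect_equal(relevance_score(TRUE, TRUE, TRUE, TRUE, FALSE), 0.8)
  expect_equal(relevance_score(TRUE, TRUE, TRUE, TRUE, TRUE), 1)
  expect_equal(relevance_score(FALSE, FALSE, FALSE, FALSE, FALSE), 0)
  expect_equal(relevance_score(c(TRUE, FALSE), c(TRUE, FALSE),
                               c(TRUE, FALSE), c(TRUE, FALSE),
                               c(FALSE, TRUE)),
               c(0.8, 0.2))
  expect_error(relevance_score(TRUE, NA, TRUE, TRUE, FALSE), "TRUE/FALSE")
})
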