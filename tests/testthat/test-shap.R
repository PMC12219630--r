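test_that("impact normalization preserves signs and is idempotent", {
  out <- normalize_impacts(c(2, -1, 1))
  expect_equal(unname(out), c(0.5, -0.25, 0.25), ignore_attr = TRUE)
  expect_equal(sum(abs(out)), 1)
  expect_false(attr(out, "degenerate"))
  # idempotent
  again <- normalize_impacts(as.numeric(out))
  expect_equal(as.numeric(again), as.numeric(out))
  # all-zero row is flagged, not divided
  zero <- normalize_impacts(c(0, 0, 0))
  expect_true(attr(zero, "degenerate"))
  expect_equal(as.numeric(zero), c(0, 0, 0))
})

test_that("SHAP feature importance averages absolute values across samples", {
  shap <- matrix(c(0.2, -0.4,
                   -0.1, 0.3),
                 nrow = 2, byrow = TRUE,
                 dimnames = list(c("a", "b"), c("f1", "f2")))
  imp <- shap_feature_importance(shap)
  expect_equal(imp$importance[imp$feature_id == "f1"], mean(c(0.2, 0.1)))
  expect_equal(imp$importance[imp$feature_id == "f2"], mean(c(0.4, 0.3)))
  expect_equal(sum(imp$pct), 100, tolerance = 1e-6)
  # one sample: importance is that row's absolute values
  one <- shap_feature_importance(shap[1, , drop = FALSE])
  expect_equal(one$importance[order(one$feature_id)], c(0.2, 0.4))
})

test_that("fuzzy labeling maps a score to floor(score x rounds) positives", {
  expect_equal(fuzzy_positive_rounds(0.22, 25), 5L)
  expect_equal(fuzzy_positive_rounds(1, 25), 25L)
  expect_equal(fuzzy_positive_rounds(0, 25), 0L)
  # monotone, and the round fraction stays within 1/n of the score
  scores <- seq(0, 1, by = 0.01)
  k <- fuzzy_positive_rounds(scores, 25)
  expect_true(all(diff(k) >= 0))
  expect_true(all(abs(k / 25 - scores) < 1 / 25))
  expect_error(fuzzy_positive_rounds(1.1, 25), "0, 1")
})

test_that("mean SHAP is additive and its importances rank planted features", {
  fx <- small_cpp()
  ids <- rownames(fx$res$matrix)[c(1:6, 21:26)]
  ms <- mean_shap(fx$res$matrix, fx$res$labels, explain_ids = ids,
                  n_rounds = 2, seed_base = 5)
  expect_lt(ms$additivity_residual, 1e-6)
  expect_equal(ms$shap_value_sum, ms$base + rowSums(ms$shap))
  # positives push above the base, negatives below
  expect_gt(mean(ms$shap_value_sum[1:6]), mean(ms$shap_value_sum[7:12]))

  imp <- shap_feature_importance(ms)
  planted <- unlist(purrr::map2(fx$sim$truth$regions$start,
                                fx$sim$truth$regions$stop, seq))
  top_feat <- fx$res$features[
    fx$res$features$feature_id == imp$feature_id[1], ]
  expect_true(any(top_feat$positions[[1]] %in% planted))

  # single model/round: the mean is that model's own SHAP row
  one <- mean_shap(fx$res$matrix, fx$res$labels, explain_ids = ids[1],
                   n_rounds = 1, seed_base = 5, models = "cart")
  expect_equal(one$n_models, 1L)
  expect_lt(one$additivity_residual, 1e-12)
})

test_that("fuzzy SHAP uses the deterministic schedule and tracks the score", {
  fx <- small_cpp()
  unl <- names(fx$res$labels)[fx$res$labels == "unlabeled"][1]
  fz <- fuzzy_shap(fx$res$matrix, fx$res$labels, protein_id = unl,
                   score = 0.22, n_rounds = 4, seed_base = 5,
                   models = c("cart", "random_forest"))
  # floor(0.22 * 4) = 0 positive rounds
  expect_equal(fz$schedule, rep("negative", 4))

  fz2 <- fuzzy_shap(fx$res$matrix, fx$res$labels, protein_id = unl,
                    score = 0.6, n_rounds = 5, seed_base = 5,
                    models = c("cart", "random_forest"))
  expect_equal(fz2$schedule,
               c(rep("positive", 3), rep("negative", 2)))
  expect_lt(fz2$additivity_residual, 1e-6)
  # a planted positive hiding in the pool, scored high, yields a high sum
  hidden <- names(fx$res$labels)[
    fx$res$labels == "unlabeled" &
      fx$sim$truth$true_class[names(fx$res$labels)] == "positive"
  ][1]
  skip_if(is.na(hidden))
  fz3 <- fuzzy_shap(fx$res$matrix, fx$res$labels, protein_id = hidden,
                    score = 0.95, n_rounds = 4, seed_base = 5,
                    models = c("cart", "random_forest"))
  expect_gt(fz3$shap_value_sum, 0.6)

  expect_error(
    fuzzy_shap(fx$res$matrix, fx$res$labels,
               protein_id = names(fx$res$labels)[1], score = 0.5),
    "already labeled"
  )
})

test_that("explanation tables rank by |impact| and conserve the row total", {
  fx <- small_cpp()
  ids <- rownames(fx$res$matrix)[1:2]
  ms <- mean_shap(fx$res$matrix, fx$res$labels, explain_ids = ids,
                  n_rounds = 1, seed_base = 5,
                  models = c("cart", "gradient_boosting"))
  et <- explanation_tables(ms, fx$res$features, id = ids[1], top_n = 15)
  row <- ms$shap[ids[1], fx$res$features$feature_id]
  expect_equal(sum(abs(et$ranking$impact)),
               sum(sort(abs(row), decreasing = TRUE)[1:15]))
  expect_equal(sum(et$profile$impact), sum(row), tolerance = 1e-9)
  expect_true(all(c("subcategory", "position") %in%
                    names(et$heatmap_impact)))
})
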