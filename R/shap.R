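# tree model configurations used for the explanation layer; gradient
# boosting is fit on the squared-error objective so all four models emit
# probability-scale outputs and their attributions can be averaged
shap_model_params <- list(
  cart = list(cp = 0.01),
  random_forest = list(ntree = 50),
  extra_trees = list(num_trees = 50),
  gradient_boosting = list(nrounds = 30, max_depth = 3,
                           objective = "reg:squarederror")
)

fit_and_shap <- function(model_id, X_fit, y_fit, X_explain, registry) {
  mi <- match(model_id, registry$model_id)
  fit <- registry$fit[[mi]](X_fit, y_fit, shap_model_params[[model_id]])
  ens <- extract_trees(model_id, fit, X_fit, colnames(X_fit))
  tree_shap(ens, X_explain)
}

#' Mean tree-SHAP feature impact over models and rounds
#'
#' The explanation layer of the pipeline: in each seeded round the four
#' tree-based model types are re-trained on the complete labeled training
#' dataset, SHAP values are computed for every requested sample, and the
#' per-feature values are averaged across models and rounds. Additivity
#' holds per underlying model (base value plus a row's SHAP values equals
#' that model's output to well below 1e-6); the averaged table inherits it
#' with respect to the averaged model output.
#'
#' @param X Feature matrix with sample ids as row names (e.g. from
#'   [cpp_run()]); `NA` mean-imputed.
#' @param labels Named label vector; `"positive"`/`"negative"` rows form
#'   the training data.
#' @param explain_ids Rows to explain (default: the labeled rows).
#' @param n_rounds Training rounds (default 5).
#' @param seed_base Base seed; round `r` seeds with `seed_base + r`.
#' @param models Tree-based model ids to use (default all four).
#' @return An object of class `impact_result`: list with `shap` (samples x
#'   features mean SHAP matrix, original feature ids), `base` (mean base
#'   value), `prediction` (mean model output per sample), `shap_value_sum`
#'   (base + row sums), `n_models`, and `additivity_residual` (max per
#'   model/sample).
#' @export
mean_shap <- function(X, labels, explain_ids = NULL, n_rounds = 5,
                      seed_base = 42,
                      models = c("cart", "random_forest", "extra_trees",
                                 "gradient_boosting")) {
  registry <- model_registry()
  bad <- setdiff(models, registry$model_id[registry$tree_based])
  if (length(bad) > 0) {
    abort(paste0("not tree-based: ", paste(bad, collapse = ", ")))
  }
  labels <- labels[rownames(X)]
  lab_ids <- rownames(X)[labels %in% c("positive", "negative")]
  explain_ids <- explain_ids %||% lab_ids
  fmap <- sanitize_features(colnames(X))
  Xs <- impute_na(X)
  colnames(Xs) <- unname(fmap)
  X_fit0 <- Xs[lab_ids, , drop = FALSE]
  y_fit <- as.integer(labels[lab_ids] == "positive")
  X_explain <- Xs[explain_ids, , drop = FALSE]

  acc <- matrix(0, nrow = length(explain_ids), ncol = ncol(Xs),
                dimnames = list(explain_ids, names(fmap)))
  base_acc <- 0
  pred_acc <- numeric(length(explain_ids))
  resid <- 0
  k <- 0L
  for (r in seq_len(n_rounds)) {
    for (model_id in models) {
      set.seed(seed_base + r)
      ts <- fit_and_shap(model_id, X_fit0, y_fit, X_explain, registry)
      acc <- acc + ts$shap
      base_acc <- base_acc + ts$base
      pred_acc <- pred_acc + ts$prediction
      resid <- max(resid,
                   max(abs(ts$base + rowSums(ts$shap) - ts$prediction)))
      k <- k + 1L
    }
  }
  shap <- acc / k
  base <- base_acc / k
  pred <- pred_acc / k
  structure(
    list(
      shap = shap, base = base,
      prediction = setNames(pred, explain_ids),
      shap_value_sum = setNames(base + rowSums(shap), explain_ids),
      n_models = k,
      additivity_residual = resid,
      models = models, n_rounds = n_rounds, seed_base = seed_base
    ),
    class = "impact_result"
  )
}

#' @export
print.impact_result <- function(x, ...) {
  cat("<impact_result>\n")
  cat("  samples:", nrow(x$shap), "| features:", ncol(x$shap),
      "| models x rounds:", x$n_models, "\n")
  cat("  base value:", round(x$base, 4),
      "| max additivity residual:", format(x$additivity_residual), "\n")
  invisible(x)
}

#' Normalize a SHAP row to signed impact shares
#'
#' Divides each value of a sample's mean-SHAP row by the sum of its
#' absolute values, so the absolute normalized impacts sum to 1 while signs
#' are preserved. An all-zero row is returned unchanged with a
#' `degenerate` attribute. Idempotent.
#'
#' @param row Numeric vector of SHAP values (a row of an
#'   `impact_result$shap` matrix).
#' @return The normalized row; attribute `degenerate` is `TRUE` for an
#'   all-zero input.
#' @export
normalize_impacts <- function(row) {
  total <- sum(abs(row))
  if (total == 0) {
    attr(row, "degenerate") <- TRUE
    return(row)
  }
  out <- row / total
  attr(out, "degenerate") <- FALSE
  out
}

#' SHAP-based feature importance
#'
#' The mean absolute SHAP value per feature over all explained samples,
#' also expressed as a percentage of the total.
#'
#' @param impact An `impact_result` from [mean_shap()] (or a SHAP matrix).
#' @return A tibble `feature_id`, `importance`, `pct` (summing to 100),
#'   sorted descending.
#' @export
shap_feature_importance <- function(impact) {
  shap <- if (inherits(impact, "impact_result")) impact$shap else impact
  imp <- colMeans(abs(shap))
  tibble(
    feature_id = names(imp),
    importance = unname(imp),
    pct = 100 * unname(imp) / sum(imp)
  ) |>
    arrange(desc(.data$importance))
}

#' Positive rounds under fuzzy labeling
#'
#' When explaining a protein absent from the training labels, the protein
#' joins the training data with a label that flips between rounds: it is
#' positive in `floor(score * n_rounds)` rounds and negative otherwise, so
#' its positive-label frequency tracks its prediction score (a score of
#' 22% over 25 rounds gives 5 positive rounds). Monotone in the score and
#' exact at 0 and 1.
#'
#' @param score Prediction score in `[0, 1]`.
#' @param n_rounds Number of training rounds.
#' @return Integer count of positive-label rounds.
#' @export
fuzzy_positive_rounds <- function(score, n_rounds) {
  if (any(score < 0 | score > 1)) abort("score must be in [0, 1]")
  if (n_rounds < 1) abort("n_rounds must be >= 1")
  as.integer(floor(score * n_rounds))
}

#' Tree-SHAP explanation of an unlabeled protein via fuzzy labeling
#'
#' Includes an unlabeled protein in the training data over `n_rounds`
#' rounds, labeling it positive in the first [fuzzy_positive_rounds()]
#' rounds and negative in the rest (deterministic schedule; the per-round
#' seeds still vary the models). The four tree model types are retrained
#' each round and SHAP values averaged as in [mean_shap()]. The resulting
#' SHAP output (`shap_value_sum`) tracks the protein's prediction score.
#'
#' @inheritParams mean_shap
#' @param protein_id Id of the protein to explain; must be unlabeled.
#' @param score The protein's substrate prediction score.
#' @return An `impact_result` for the single protein, with `schedule` (the
#'   per-round labels) attached.
#' @export
fuzzy_shap <- function(X, labels, protein_id, score, n_rounds = 25,
                       seed_base = 42,
                       models = c("cart", "random_forest", "extra_trees",
                                  "gradient_boosting")) {
  labels <- labels[rownames(X)]
  if (!protein_id %in% rownames(X)) abort("protein not in the matrix")
  if (labels[protein_id] %in% c("positive", "negative")) {
    abort("protein is already labeled; use mean_shap() directly")
  }
  registry <- model_registry()
  n_pos_rounds <- fuzzy_positive_rounds(score, n_rounds)
  schedule <- rep(c("positive", "negative"),
                  c(n_pos_rounds, n_rounds - n_pos_rounds))

  lab_ids <- rownames(X)[labels %in% c("positive", "negative")]
  fmap <- sanitize_features(colnames(X))
  Xs <- impute_na(X)
  colnames(Xs) <- unname(fmap)
  X_explain <- Xs[protein_id, , drop = FALSE]

  acc <- matrix(0, nrow = 1, ncol = ncol(Xs),
                dimnames = list(protein_id, names(fmap)))
  base_acc <- 0
  pred_acc <- 0
  resid <- 0
  k <- 0L
  for (r in seq_len(n_rounds)) {
    fit_ids <- c(lab_ids, protein_id)
    y_fit <- as.integer(c(labels[lab_ids] == "positive",
                          schedule[r] == "positive"))
    X_fit <- Xs[fit_ids, , drop = FALSE]
    for (model_id in models) {
      set.seed(seed_base + r)
      ts <- fit_and_shap(model_id, X_fit, y_fit, X_explain, registry)
      acc <- acc + ts$shap
      base_acc <- base_acc + ts$base
      pred_acc <- pred_acc + ts$prediction
      resid <- max(resid,
                   max(abs(ts$base + rowSums(ts$shap) - ts$prediction)))
      k <- k + 1L
    }
  }
  shap <- acc / k
  base <- base_acc / k
  structure(
    list(
      shap = shap, base = base,
      prediction = setNames(pred_acc / k, protein_id),
      shap_value_sum = setNames(base + rowSums(shap), protein_id),
      n_models = k,
      additivity_residual = resid,
      models = models, n_rounds = n_rounds, seed_base = seed_base,
      schedule = schedule, score = score
    ),
    class = "impact_result"
  )
}

#' Per-residue explanation tables for one protein
#'
#' Builds the data products behind the explanation plots: the ranking table
#' (features sorted by absolute impact, with sign, subcategory, reference
#' positions, and mean difference), the per-residue impact profile (each
#' feature's impact split equally over its positions; the profile total
#' equals the summed impacts), and the per-(subcategory, position)
#' heatmap tables of mean difference and impact.
#'
#' @param impact An `impact_result`.
#' @param features Feature tibble with `feature_id`, `positions`,
#'   `subcategory`, `mean_dif` (e.g. `tidy()` is not needed; pass
#'   `cpp$features`).
#' @param id Sample id to explain (default the first explained row).
#' @param top_n Rows in the ranking table (default 15).
#' @return A list with `ranking`, `profile`, `heatmap_mean_dif`,
#'   `heatmap_impact`.
#' @export
explanation_tables <- function(impact, features, id = NULL, top_n = 15) {
  id <- id %||% rownames(impact$shap)[1]
  if (!id %in% rownames(impact$shap)) abort(paste0("no SHAP row for ", id))
  row <- impact$shap[id, ]
  feats <- features |>
    mutate(impact = unname(row[.data$feature_id])) |>
    arrange(desc(abs(.data$impact)))
  ranking <- feats |>
    head(top_n) |>
    mutate(rank = row_number(),
           positions_str = map_chr(.data$positions,
                                   ~ paste(.x, collapse = ","))) |>
    select("rank", "feature_id", "impact", "subcategory",
           "mean_dif", "positions_str")
  agg <- positional_aggregation(feats, importance = "impact")
  list(
    ranking = ranking,
    profile = rename(agg$profile, impact = "importance"),
    heatmap_mean_dif = select(agg$feature_map, "subcategory", "position",
                              "mean_dif"),
    heatmap_impact = select(agg$feature_map, "subcategory", "position",
                            impact = "importance")
  )
}
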