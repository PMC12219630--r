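# stratified fold assignment: within each class, shuffle then deal into k
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

sanitize_features <- function(feature_ids) {
  setNames(sprintf("f%05d", seq_along(feature_ids)), feature_ids)
}

#' Monte Carlo nested-CV training over the model registry
#'
#' The ensemble learning strategy: in each of `n_rounds` seeded rounds the
#' labeled data are split into a stratified 80/20 train/test partition;
#' features are ranked by random-forest importance on the training split;
#' and for every registry model the number of pre-selected top-ranked
#' features (over `top_k_grid`) and the model's hyperparameters are chosen
#' by stratified `cv_folds`-fold cross-validated balanced accuracy on the
#' training split. The winning configuration is refit on the full training
#' split and evaluated on the held-out test split. The default
#' configuration (25 rounds, 10 models) fits 250 final models.
#'
#' @param X Numeric feature matrix (samples x features, ids as row/col
#'   names), e.g. the matrix of a [cpp_run()] result. `NA` cells are
#'   mean-imputed.
#' @param labels Named vector over the rows of `X`; only `"positive"` and
#'   `"negative"` rows are used for training.
#' @param registry Model registry (default [model_registry()]).
#' @param n_rounds Number of Monte Carlo rounds (default 25).
#' @param test_fraction Held-out fraction per round (default 0.2).
#' @param cv_folds Inner cross-validation folds (default 5).
#' @param top_k_grid Feature pre-selection sizes to optimize over (default
#'   `c(50, 100)`, capped at the number of available features).
#' @param seed_base Base seed; round `r` uses `seed_base + r`.
#' @return An object of class `cpp_ensemble`: per-round fits, held-out
#'   predictions and metrics, the feature-name mapping, and the
#'   configuration. Use [predict_score()], [evaluate_bundle()],
#'   [tree_feature_importance()], [tidy.cpp_ensemble()].
#' @export
monte_carlo_train <- function(X, labels, registry = model_registry(),
                              n_rounds = 25, test_fraction = 0.2,
                              cv_folds = 5, top_k_grid = c(50, 100),
                              seed_base = 42) {
  if (n_rounds < 1) abort("n_rounds must be >= 1")
  if (test_fraction <= 0 || test_fraction >= 1) {
    abort("test_fraction must be in (0, 1)")
  }
  labels <- labels[rownames(X)]
  lab_ids <- rownames(X)[labels %in% c("positive", "negative")]
  if (length(unique(labels[lab_ids])) < 2) {
    abort("need both positive and negative labels")
  }
  fmap <- sanitize_features(colnames(X))
  Xl <- impute_na(X[lab_ids, , drop = FALSE])
  colnames(Xl) <- unname(fmap)
  y <- as.integer(labels[lab_ids] == "positive")
  names(y) <- lab_ids
  top_k_grid <- sort(unique(pmin(top_k_grid, ncol(Xl))))

  rounds <- vector("list", n_rounds)
  for (r in seq_len(n_rounds)) {
    set.seed(seed_base + r)
    test_idx <- unlist(lapply(split(seq_along(y), y), function(idx) {
      sample(idx, max(1, round(test_fraction * length(idx))))
    }))
    train_idx <- setdiff(seq_along(y), test_idx)
    y_tr <- y[train_idx]
    y_te <- y[test_idx]
    if (length(unique(y_tr)) < 2 || length(unique(y_te)) < 2) {
      abort(paste0("round ", r, ": a class is absent from a split"))
    }
    X_tr <- Xl[train_idx, , drop = FALSE]
    X_te <- Xl[test_idx, , drop = FALSE]

    ranker <- randomForest::randomForest(x = X_tr,
                                         y = factor(y_tr, levels = c(0, 1)),
                                         ntree = 100)
    rank_order <- order(-randomForest::importance(ranker)[, 1])
    fold <- stratified_folds(y_tr, cv_folds)

    fits <- vector("list", nrow(registry))
    for (mi in seq_len(nrow(registry))) {
      fit_fn <- registry$fit[[mi]]
      pred_fn <- registry$predict[[mi]]
      best <- NULL
      for (k in top_k_grid) {
        feats <- colnames(X_tr)[rank_order[seq_len(k)]]
        for (params in registry$grid[[mi]]) {
          cv_ba <- mean(vapply(seq_len(cv_folds), function(f) {
            tr <- fold != f
            fit <- fit_fn(X_tr[tr, feats, drop = FALSE], y_tr[tr], params)
            p <- pred_fn(fit, X_tr[!tr, feats, drop = FALSE])
            balanced_accuracy(y_tr[!tr] == 1, p >= 0.5)
          }, numeric(1)))
          if (is.null(best) || cv_ba > best$cv_ba) {
            best <- list(cv_ba = cv_ba, k = k, params = params, feats = feats)
          }
        }
      }
      fit <- fit_fn(X_tr[, best$feats, drop = FALSE], y_tr, best$params)
      p_te <- pred_fn(fit, X_te[, best$feats, drop = FALSE])
      fits[[mi]] <- list(
        model_id = registry$model_id[mi],
        fit = fit, features = best$feats, params = best$params,
        k = best$k, cv_ba = best$cv_ba,
        test_prob = setNames(p_te, names(y_te)),
        test_ba = balanced_accuracy(y_te == 1, p_te >= 0.5)
      )
    }
    rounds[[r]] <- list(
      seed = seed_base + r,
      train_ids = names(y_tr),
      test_ids = names(y_te),
      fits = fits
    )
  }
  structure(
    list(
      rounds = rounds,
      registry = registry,
      feature_map = fmap,
      labeled_ids = lab_ids,
      y = y,
      config = list(n_rounds = n_rounds, test_fraction = test_fraction,
                    cv_folds = cv_folds, top_k_grid = top_k_grid,
                    seed_base = seed_base)
    ),
    class = "cpp_ensemble"
  )
}

#' @export
print.cpp_ensemble <- function(x, ...) {
  n_fits <- sum(lengths(lapply(x$rounds, `[[`, "fits")))
  cat("<cpp_ensemble>\n")
  cat("  rounds:", length(x$rounds), "| final models:", n_fits, "\n")
  cat("  mean held-out balanced accuracy:",
      round(mean(tidy(x)$test_ba), 3), "\n")
  invisible(x)
}

#' @describeIn monte_carlo_train Per-round, per-model metric table.
#' @param x A `cpp_ensemble`.
#' @param ... Unused.
#' @export
tidy.cpp_ensemble <- function(x, ...) {
  bind_rows(imap(x$rounds, function(rd, r) {
    tibble(
      round = r,
      model_id = map_chr(rd$fits, "model_id"),
      k = map_int(rd$fits, ~ as.integer(.x$k)),
      cv_ba = map_dbl(rd$fits, "cv_ba"),
      test_ba = map_dbl(rd$fits, "test_ba")
    )
  }))
}

#' @describeIn monte_carlo_train One-row summary (model count, mean
#'   held-out balanced accuracy).
#' @export
glance.cpp_ensemble <- function(x, ...) {
  tt <- tidy(x)
  tibble(
    n_rounds = length(x$rounds),
    n_models = nrow(tt),
    mean_test_ba = mean(tt$test_ba),
    sd_test_ba = sd(tt$test_ba)
  )
}

#' Aggregated substrate prediction scores
#'
#' Averages the predicted positive-class probability over the ensemble's
#' models. For proteins that were part of the training data, only rounds in
#' which the protein was held out contribute (out-of-fold discipline);
#' proteins unseen during training receive predictions from every round.
#'
#' @param bundle A `cpp_ensemble`.
#' @param X Feature matrix covering at least the ensemble's feature space;
#'   rows are the proteins to score.
#' @return A tibble `id`, `score`, `n_models` (contributing model count),
#'   `confidence` (see [confidence_class()]).
#' @export
predict_score <- function(bundle, X) {
  missing_feats <- setdiff(names(bundle$feature_map), colnames(X))
  if (length(missing_feats) > 0) {
    abort(paste0("missing features: ",
                 paste(head(missing_feats, 3), collapse = ", "),
                 if (length(missing_feats) > 3) " ..."))
  }
  Xs <- impute_na(X[, names(bundle$feature_map), drop = FALSE])
  colnames(Xs) <- unname(bundle$feature_map)
  ids <- rownames(Xs)
  acc <- matrix(0, nrow = length(ids), ncol = 2,
                dimnames = list(ids, c("sum", "n")))
  for (rd in bundle$rounds) {
    eligible <- !(ids %in% rd$train_ids)
    if (!any(eligible)) next
    rows <- which(eligible)
    for (ft in rd$fits) {
      p <- bundle$registry$predict[[match(ft$model_id, bundle$registry$model_id)]](
        ft$fit, Xs[rows, ft$features, drop = FALSE]
      )
      acc[rows, "sum"] <- acc[rows, "sum"] + p
      acc[rows, "n"] <- acc[rows, "n"] + 1
    }
  }
  starved <- acc[, "n"] == 0
  if (any(starved)) {
    warn(paste0(sum(starved), " training protein(s) never held out; ",
                "score is NA"))
  }
  tibble(
    id = ids,
    score = ifelse(starved, NA_real_, acc[, "sum"] / acc[, "n"]),
    n_models = as.integer(acc[, "n"])
  ) |>
    mutate(confidence = confidence_class(.data$score))
}

#' Aggregate prediction scores across approaches
#'
#' Combines per-approach scores (e.g. the best approach per
#' dataset-annotation combination) into a final prediction score: the mean,
#' with the sample (n-1) standard deviation reflecting variability across
#' approaches, and the confidence class of the mean.
#'
#' @param scores A data frame with `id` and one score column per approach,
#'   or a long tibble with columns `id`, `approach`, `score`.
#' @return A tibble `id`, `score`, `sd`, `n_approaches`, `confidence`.
#' @export
aggregate_approaches <- function(scores) {
  scores <- as_tibble(scores)
  if (all(c("approach", "score") %in% names(scores))) {
    long <- scores
  } else {
    long <- tidyr::pivot_longer(scores, -"id", names_to = "approach",
                                values_to = "score")
  }
  long |>
    group_by(.data$id) |>
    summarise(
      sd = if (n() > 1) stats::sd(.data$score) else 0,
      n_approaches = n(),
      score = mean(.data$score),
      .groups = "drop"
    ) |>
    mutate(confidence = confidence_class(.data$score)) |>
    select("id", "score", "sd", "n_approaches", "confidence")
}

#' Confidence-based substrate classes
#'
#' Maps a prediction score in `[0, 1]` to the four confidence classes:
#' high-confidence substrate (score >= 0.8), low-confidence substrate
#' (0.5 <= score < 0.8), low-confidence non-substrate (0.2 < score < 0.5),
#' high-confidence non-substrate (score <= 0.2).
#'
#' @param score Numeric vector in `[0, 1]` (`NA` allowed).
#' @return Character vector of class labels.
#' @export
confidence_class <- function(score) {
  if (any(score < 0 | score > 1, na.rm = TRUE)) {
    abort("scores must be in [0, 1]")
  }
  dplyr::case_when(
    is.na(score) ~ NA_character_,
    score >= 0.8 ~ "HC substrate",
    score >= 0.5 ~ "LC substrate",
    score > 0.2 ~ "LC non-substrate",
    TRUE ~ "HC non-substrate"
  )
}

#' Averaged tree-model feature importance
#'
#' Per-model impurity importances (normalized to sum 1 within each model)
#' averaged over every tree-based final model of every round, renormalized
#' to sum 1. With the default 25 rounds and 4 tree-based model types this
#' averages 100 importance vectors.
#'
#' @param bundle A `cpp_ensemble`.
#' @return A tibble `feature_id`, `importance`, sorted descending;
#'   importances sum to 1.
#' @export
tree_feature_importance <- function(bundle) {
  tree_ids <- bundle$registry$model_id[bundle$registry$tree_based]
  feature_names <- unname(bundle$feature_map)
  vecs <- list()
  for (rd in bundle$rounds) {
    for (ft in rd$fits) {
      if (!ft$model_id %in% tree_ids) next
      vecs[[length(vecs) + 1L]] <-
        model_importance(ft$model_id, ft$fit, feature_names)
    }
  }
  if (length(vecs) == 0) abort("no tree-based models in the bundle")
  avg <- Reduce(`+`, vecs) / length(vecs)
  if (sum(avg) > 0) avg <- avg / sum(avg)
  tibble(
    feature_id = names(bundle$feature_map)[match(names(avg),
                                                 bundle$feature_map)],
    importance = unname(avg)
  ) |>
    arrange(desc(.data$importance))
}

#' Held-out evaluation of an ensemble
#'
#' Balanced accuracy (mean of sensitivity and specificity) with confusion
#' counts, per model type, aggregated over the held-out predictions of all
#' rounds.
#'
#' @param bundle A `cpp_ensemble`.
#' @return A tibble with per-model `tp`, `fn`, `tn`, `fp`,
#'   `balanced_accuracy`, plus an `overall` row.
#' @export
evaluate_bundle <- function(bundle) {
  rows <- list()
  for (rd in bundle$rounds) {
    truth <- bundle$y[rd$test_ids] == 1
    for (ft in rd$fits) {
      pred <- ft$test_prob >= 0.5
      rows[[length(rows) + 1L]] <- tibble(
        model_id = ft$model_id,
        tp = sum(pred & truth), fn = sum(!pred & truth),
        tn = sum(!pred & !truth), fp = sum(pred & !truth)
      )
    }
  }
  per_model <- bind_rows(rows) |>
    group_by(.data$model_id) |>
    summarise(across(c("tp", "fn", "tn", "fp"), sum), .groups = "drop")
  all_row <- per_model |>
    summarise(model_id = "overall", across(c("tp", "fn", "tn", "fp"), sum))
  bind_rows(per_model, all_row) |>
    mutate(balanced_accuracy =
             (.data$tp / (.data$tp + .data$fn) +
                .data$tn / (.data$tn + .data$fp)) / 2)
}

#' Leave-one-out cross-validation of one model type
#'
#' Refits the given registry model once per left-out labeled sample and
#' reports the confusion counts and balanced accuracy of the held-out
#' predictions.
#'
#' @param X Feature matrix with ids as row names.
#' @param labels Named label vector (`"positive"`/`"negative"` rows used).
#' @param model_id Registry model to evaluate (default `"svm_rbf"`).
#' @param params Hyperparameters for the fit (default first grid entry).
#' @param seed Seed set before each refit.
#' @return A one-row tibble `tp`, `fn`, `tn`, `fp`, `balanced_accuracy`.
#' @export
evaluate_loocv <- function(X, labels, model_id = "svm_rbf", params = NULL,
                           seed = 42) {
  registry <- model_registry()
  mi <- match(model_id, registry$model_id)
  if (is.na(mi)) abort(paste0("unknown model: ", model_id))
  params <- params %||% registry$grid[[mi]][[1]]
  labels <- labels[rownames(X)]
  ids <- rownames(X)[labels %in% c("positive", "negative")]
  if (length(unique(labels[ids])) < 2) abort("need both classes")
  Xl <- impute_na(X[ids, , drop = FALSE])
  colnames(Xl) <- unname(sanitize_features(colnames(Xl)))
  y <- as.integer(labels[ids] == "positive")
  pred <- vapply(seq_along(ids), function(i) {
    set.seed(seed)
    fit <- registry$fit[[mi]](Xl[-i, , drop = FALSE], y[-i], params)
    registry$predict[[mi]](fit, Xl[i, , drop = FALSE])
  }, numeric(1))
  tibble(
    tp = sum(pred >= 0.5 & y == 1), fn = sum(pred < 0.5 & y == 1),
    tn = sum(pred < 0.5 & y == 0), fp = sum(pred >= 0.5 & y == 0)
  ) |>
    mutate(balanced_accuracy =
             (.data$tp / (.data$tp + .data$fn) +
                .data$tn / (.data$tn + .data$fp)) / 2)
}

#' Relevance score of a predicted substrate
#'
#' The mean of five binary relevance factors: a new pathway link, a new
#' disease link, mutations within the TMD-JMD, membership in a protein
#' family not represented among known substrates, and a TMD-JMD sequence
#' dissimilar (no more than 30% identity) to any known substrate. Four true
#' factors out of five give 0.8.
#'
#' @param new_pathway_link,new_disease_link,mutated_tmd_jmd,new_protein_family,dissimilar_tmd_jmd
#'   Logical vectors (recycled to a common length).
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
relevance_score <- function(new_pathway_link, new_disease_link,
                            mutated_tmd_jmd, new_protein_family,
                            dissimilar_tmd_jmd) {
  factors <- cbind(new_pathway_link, new_disease_link, mutated_tmd_jmd,
                   new_protein_family, dissimilar_tmd_jmd)
  if (anyNA(factors)) abort("relevance factors must be TRUE/FALSE")
  rowMeans(factors)
}
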