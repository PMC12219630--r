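region_boundaries <- function(jmd_len = 10, tmd_len_ref = 20) {
  c(jmd_len + 0.5, jmd_len + tmd_len_ref + 0.5)
}

#' Per-residue importance profile plot
#'
#' Bar profile of cumulative feature importance (or impact) per residue
#' position on the JMD-N | TMD | JMD-C reference frame, with the membrane
#' boundaries marked.
#'
#' @param profile Profile tibble (`position`, `region`, and an
#'   `importance` or `impact` column) from [positional_aggregation()] or
#'   [explanation_tables()].
#' @param jmd_len,tmd_len_ref Frame geometry.
#' @return A ggplot object.
#' @export
plot_cpp_profile <- function(profile, jmd_len = 10, tmd_len_ref = 20) {
  value_col <- if ("importance" %in% names(profile)) "importance" else "impact"
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$position, y = .data[[value_col]],
                               fill = .data$region)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = region_boundaries(jmd_len, tmd_len_ref),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_fill_manual(values = c(jmd_n = "#7fb2d6", tmd = "#2c6e91",
                                          jmd_c = "#7fb2d6")) +
    ggplot2::labs(x = "position (JMD-N | TMD | JMD-C)", y = value_col) +
    ggplot2::theme_minimal()
}

#' Feature-map heatmap
#'
#' Tile map of the per-(scale subcategory, position) mean difference
#' between test and reference proteins, the tabular form of the profiling
#' heatmap.
#'
#' @param feature_map Tibble (`subcategory`, `position`, `mean_dif`) from
#'   [positional_aggregation()].
#' @param jmd_len,tmd_len_ref Frame geometry.
#' @return A ggplot object.
#' @export
plot_cpp_feature_map <- function(feature_map, jmd_len = 10, tmd_len_ref = 20) {
  ggplot2::ggplot(feature_map,
                  ggplot2::aes(x = .data$position, y = .data$subcategory,
                               fill = .data$mean_dif)) +
    ggplot2::geom_tile() +
    ggplot2::geom_vline(xintercept = region_boundaries(jmd_len, tmd_len_ref),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = "position (JMD-N | TMD | JMD-C)", y = NULL,
                  fill = "mean diff") +
    ggplot2::theme_minimal()
}

#' Impact ranking plot
#'
#' Signed horizontal bars of the top features' SHAP impacts for one
#' protein.
#'
#' @param ranking Ranking tibble from [explanation_tables()].
#' @return A ggplot object.
#' @export
plot_shap_ranking <- function(ranking) {
  ranking <- mutate(ranking,
                    feature_id = factor(.data$feature_id,
                                        levels = rev(.data$feature_id)))
  ggplot2::ggplot(ranking,
                  ggplot2::aes(x = .data$impact, y = .data$feature_id,
                               fill = .data$impact > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#b2182b",
                                          `FALSE` = "#2166ac")) +
    ggplot2::labs(x = "feature impact", y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn cpp_run Profile plot of the accepted features (importance =
#'   absolute adjusted AUC when no importance column is present).
#' @param object A `cpp_result`.
#' @export
autoplot.cpp_result <- function(object, ...) {
  feats <- object$features
  if (!"importance" %in% names(feats)) {
    feats$importance <- abs(feats$adjusted_auc)
  }
  agg <- positional_aggregation(feats,
                                jmd_len = object$config$jmd_len,
                                tmd_len_ref = object$config$tmd_len_ref)
  plot_cpp_profile(agg$profile, jmd_len = object$config$jmd_len,
                   tmd_len_ref = object$config$tmd_len_ref)
}

#' @describeIn monte_carlo_train Box plot of held-out balanced accuracy per
#'   model type.
#' @param object A `cpp_ensemble`.
#' @export
autoplot.cpp_ensemble <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$model_id, y = .data$test_ba)) +
    ggplot2::geom_boxplot(fill = "#7fb2d6") +
    ggplot2::labs(x = NULL, y = "held-out balanced accuracy") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
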