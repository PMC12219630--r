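#' Create the exhaustive CPP feature space
#'
#' A CPP feature is a part-split-scale combination. This enumerates the full
#' Cartesian product in a fixed order (part-major, then split, then scale),
#' giving stable feature ids; with the three default parts, the 330 default
#' splits, and a 133-scale set this creates 131,670 features.
#'
#' @param parts Character vector of part ids (default the three parts
#'   covering the TMD and both juxtamembrane transitions).
#' @param splits Split table from [cpp_splits()].
#' @param scales Normalized scale tibble.
#' @return A tibble with `feature_id`, `part`, `split_id`, `scale_id`.
#' @export
cpp_feature_space <- function(parts = cpp_default_parts(), splits = cpp_splits(),
                              scales) {
  if (length(parts) == 0 || nrow(splits) == 0 || nrow(scales) == 0) {
    abort("parts, splits, and scales must be non-empty")
  }
  grid <- tidyr::expand_grid(part = parts, split_id = splits$split_id,
                             scale_id = scales$scale_id)
  mutate(grid,
         feature_id = paste(.data$part, .data$split_id, .data$scale_id, sep = "|"),
         .before = 1)
}

#' Default CPP parts
#'
#' The part set used for profiling: the TMD plus the two combined parts
#' spanning the N- and C-terminal membrane transitions.
#'
#' @return Character vector of three part ids.
#' @export
cpp_default_parts <- function() c("tmd", "jmd_n_tmd_n", "tmd_c_jmd_c")

# L x n_splits weight matrix: column j averages the residues selected by
# split j on a part of length L; NA-columns marked in the "na" attribute.
split_weights <- function(splits, L) {
  idx <- resolve_splits(splits, L)
  W <- matrix(0, nrow = L, ncol = nrow(splits))
  na <- vapply(idx, is.null, logical(1))
  for (j in which(!na)) W[idx[[j]], j] <- 1 / length(idx[[j]])
  attr(W, "na") <- na
  W
}

#' Compute the samples-by-features CPP matrix
#'
#' Materializes the feature definition: each cell is the mean normalized
#' scale value over the split-selected residues of that protein's part.
#' Cells where a split exceeds the part length are `NA` (not applicable),
#' never 0. Fully deterministic.
#'
#' @param parts_tbl Output of [derive_parts()].
#' @param parts,splits,scales Feature-space axes (see [cpp_feature_space()]).
#' @return A numeric matrix (rows = protein ids, columns = feature ids) with
#'   values in `[0, 1]` or `NA`.
#' @export
cpp_feature_matrix <- function(parts_tbl, parts = cpp_default_parts(),
                               splits = cpp_splits(), scales) {
  n <- nrow(parts_tbl)
  n_split <- nrow(splits)
  n_scale <- nrow(scales)
  S <- scale_matrix(scales) # 20 x n_scale
  X <- matrix(NA_real_, nrow = n,
              ncol = length(parts) * n_split * n_scale,
              dimnames = list(parts_tbl$id, cpp_feature_space(parts, splits, scales)$feature_id))

  for (pi in seq_along(parts)) {
    part <- parts[[pi]]
    part_seqs <- parts_tbl[[part]]
    lens <- nchar(part_seqs)
    col_base <- (pi - 1L) * n_split * n_scale
    for (L in unique(lens)) {
      rows <- which(lens == L)
      C <- matrix(0L, nrow = length(rows), ncol = L)
      for (r in seq_along(rows)) C[r, ] <- encode_sequence(part_seqs[rows[r]])
      W <- split_weights(splits, L)
      na_splits <- attr(W, "na")
      for (si in seq_len(n_scale)) {
        V <- matrix(S[, si][C], nrow = length(rows)) # n_rows x L scale values
        block <- V %*% W                             # n_rows x n_split
        block[, na_splits] <- NA_real_
        cols <- col_base + (seq_len(n_split) - 1L) * n_scale + si
        X[rows, cols] <- block
      }
    }
  }
  X
}

#' Adjusted AUC between two samples
#'
#' Rank-sum (Mann-Whitney) AUC of the test sample against the reference
#' sample, with ties counted one half, shifted by -0.5 to lie in
#' `[-0.5, 0.5]`. The extremes are reached exactly when all test values are
#' higher (+0.5) or lower (-0.5) than all reference values; positive values
#' mean the test set runs systematically higher.
#'
#' @param test,ref Non-empty numeric vectors.
#' @return A number in `[-0.5, 0.5]`.
#' @export
adjusted_auc <- function(test, ref) {
  test <- test[!is.na(test)]
  ref <- ref[!is.na(ref)]
  n1 <- length(test)
  n2 <- length(ref)
  if (n1 == 0 || n2 == 0) abort("both samples must be non-empty")
  r <- rank(c(test, ref))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  auc - 0.5
}

# per-feature stats over a feature matrix; NA cells excluded, not imputed
feature_stats <- function(space, X, test_ids, ref_ids) {
  if (length(intersect(test_ids, ref_ids)) > 0) {
    abort("test and reference sets must be disjoint")
  }
  Xt <- X[test_ids, , drop = FALSE]
  Xr <- X[ref_ids, , drop = FALSE]
  space |>
    mutate(
      mean_test = colMeans(Xt, na.rm = TRUE),
      mean_ref = colMeans(Xr, na.rm = TRUE),
      mean_dif = .data$mean_test - .data$mean_ref,
      std_test = apply(Xt, 2, sd, na.rm = TRUE)
    )
}

#' Statistical pre-filter of CPP features
#'
#' Step two of the CPP algorithm: features whose standard deviation over the
#' test samples exceeds `max_std_test` are removed, and of the survivors the
#' `floor(pct_pre_filter * n_created)` features with the largest absolute
#' mean difference between test and reference are kept (ties broken by
#' feature id). With 131,670 created features and the default
#' `pct_pre_filter = 0.05` the cut is 6,583 features. If fewer survivors
#' than the cut exist, all survivors are returned with a warning.
#'
#' @param space Feature-space tibble ([cpp_feature_space()]).
#' @param X Feature matrix ([cpp_feature_matrix()]).
#' @param test_ids,ref_ids Disjoint row-id sets defining the comparison.
#' @param max_std_test Test-set dispersion ceiling (default 0.2).
#' @param pct_pre_filter Fraction of the created space to keep (default
#'   0.05).
#' @return The surviving features with columns `mean_test`, `mean_ref`,
#'   `mean_dif`, `std_test` added.
#' @export
cpp_prefilter <- function(space, X, test_ids, ref_ids,
                          max_std_test = 0.2, pct_pre_filter = 0.05) {
  if (pct_pre_filter <= 0 || pct_pre_filter > 1) {
    abort("pct_pre_filter must be in (0, 1]")
  }
  stats <- feature_stats(space, X, test_ids, ref_ids)
  k <- floor(pct_pre_filter * nrow(space))
  survivors <- filter(stats, !is.na(.data$std_test),
                      .data$std_test <= max_std_test,
                      !is.na(.data$mean_dif))
  if (nrow(survivors) < k) {
    warn(paste0("only ", nrow(survivors), " features pass the std filter; ",
                "requested top ", k))
    k <- nrow(survivors)
  }
  survivors |>
    arrange(desc(abs(.data$mean_dif)), .data$feature_id) |>
    head(k)
}

#' Rank features by absolute adjusted AUC
#'
#' Step three of the CPP algorithm: computes the adjusted AUC for every
#' feature and sorts in descending order of its absolute value (ties by
#' absolute mean difference, then feature id).
#'
#' @inheritParams cpp_prefilter
#' @param features Pre-filtered feature tibble.
#' @return The features with `adjusted_auc` added, in rank order.
#' @export
cpp_rank <- function(features, X, test_ids, ref_ids) {
  Xt <- X[test_ids, features$feature_id, drop = FALSE]
  Xr <- X[ref_ids, features$feature_id, drop = FALSE]
  features |>
    mutate(adjusted_auc = vapply(
      seq_len(nrow(features)),
      function(j) adjusted_auc(Xt[, j], Xr[, j]),
      numeric(1)
    )) |>
    arrange(desc(abs(.data$adjusted_auc)), desc(abs(.data$mean_dif)),
            .data$feature_id)
}

#' Resolve feature positions on the reference frame
#'
#' Maps each feature's split-selected residues onto the fixed positional
#' frame used for profiles and maps: JMD-N (10) | TMD (`tmd_len_ref`,
#' default 20) | JMD-C (10), i.e. 40 positions by default. Each protein's
#' own parts may differ in length; the reference frame gives all features a
#' common axis.
#'
#' @param features Feature tibble with `part` and `split_id`.
#' @param splits Split table the `split_id`s refer to.
#' @param tmd_len_ref Reference TMD length (default 20).
#' @param jmd_len,ext_len Part configuration.
#' @return The features with a list-column `positions` of global frame
#'   indices (`NULL` where the split is inapplicable even at reference
#'   lengths).
#' @export
feature_positions <- function(features, splits = cpp_splits(), tmd_len_ref = 20,
                              jmd_len = 10, ext_len = 4) {
  split_rows <- match(features$split_id, splits$split_id)
  pos <- vector("list", nrow(features))
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(features))) {
    part <- features$part[i]
    key <- paste0(part, "#", features$split_id[i])
    if (is.null(cache[[key]])) {
      L <- part_length(part, tmd_len_ref, jmd_len, ext_len)
      idx <- resolve_split(splits[split_rows[i], ], L)
      cache[[key]] <- if (is.null(idx)) list(NULL) else
        list(tmd_jmd_position(part, idx, tmd_len_ref, jmd_len, ext_len))
    }
    pos[i] <- cache[[key]]
  }
  features$positions <- pos
  features
}

#' Redundancy filter of ranked CPP features
#'
#' Step four of the CPP algorithm: a greedy scan in rank order accepts a
#' candidate unless some already-accepted feature is positionally redundant
#' with it (Jaccard overlap of reference-frame positions above
#' `max_overlap`) and physicochemically redundant (same scale subcategory,
#' or absolute Pearson correlation of the 20-residue scale vectors above
#' `max_cor`). The scan stops once `n_filter` features are accepted, so the
#' accepted set for a smaller `n_filter` is always a prefix of the set for a
#' larger one.
#'
#' @param ranked Ranked feature tibble with `positions` (see
#'   [feature_positions()]) and `subcategory`.
#' @param scales Scale tibble covering the features' scale ids.
#' @param n_filter Maximum number of features to accept (default 100).
#' @param max_overlap Positional Jaccard ceiling (default 0.5).
#' @param max_cor Scale-correlation ceiling (default 0.5).
#' @return The accepted features, in rank order.
#' @export
cpp_redundancy_filter <- function(ranked, scales, n_filter = 100,
                                  max_overlap = 0.5, max_cor = 0.5) {
  if (n_filter < 1) abort("n_filter must be >= 1")
  if (max_overlap < 0 || max_overlap > 1 || max_cor < 0 || max_cor > 1) {
    abort("max_overlap and max_cor must be in [0, 1]")
  }
  if (!"positions" %in% names(ranked)) abort("run feature_positions() first")
  cm <- abs(suppressWarnings(cor(scale_matrix(scales))))
  subcat <- setNames(scales$subcategory, scales$scale_id)

  accepted <- integer(0)
  for (i in seq_len(nrow(ranked))) {
    pos_i <- ranked$positions[[i]]
    if (is.null(pos_i)) next
    redundant <- FALSE
    for (a in accepted) {
      pos_a <- ranked$positions[[a]]
      jac <- length(intersect(pos_i, pos_a)) / length(union(pos_i, pos_a))
      if (jac <= max_overlap) next
      same_sub <- identical(subcat[[ranked$scale_id[i]]],
                            subcat[[ranked$scale_id[a]]])
      correlated <- cm[ranked$scale_id[i], ranked$scale_id[a]] > max_cor
      if (same_sub || correlated) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) {
      accepted <- c(accepted, i)
      if (length(accepted) >= n_filter) break
    }
  }
  ranked[accepted, , drop = FALSE]
}

#' Run the full CPP algorithm
#'
#' Composition of the four CPP steps -- exhaustive feature creation,
#' statistical pre-filtering, adjusted-AUC ranking, redundancy filtering --
#' comparing a test group of proteins against a reference group. The whole
#' pipeline is deterministic: rerunning on the same inputs reproduces the
#' output exactly.
#'
#' @param data Protein annotation table (see [validate_entries()]).
#' @param scales Normalized scale tibble with subcategories.
#' @param parts Part ids to profile (default [cpp_default_parts()]).
#' @param splits Split table (default [cpp_splits()]).
#' @param test_label Label defining the test group (default `"positive"`).
#' @param ref_labels Labels defining the reference group (default
#'   `c("negative", "unlabeled")`).
#' @param n_filter,max_std_test,pct_pre_filter,max_overlap,max_cor CPP
#'   parameters; defaults 100, 0.2, 0.05, 0.5, 0.5.
#' @param tmd_len_ref Reference TMD length for the positional frame.
#' @param jmd_len,ext_len Part configuration.
#' @return An object of class `cpp_result`: a list with `features` (the
#'   accepted, ranked features with stats and positions), `matrix` (samples
#'   by accepted features), `labels`, counts of each stage, and the
#'   configuration. Use [tidy.cpp_result()], [glance.cpp_result()],
#'   [autoplot.cpp_result()].
#' @export
cpp_run <- function(data, scales, parts = cpp_default_parts(),
                    splits = cpp_splits(), test_label = "positive",
                    ref_labels = c("negative", "unlabeled"), n_filter = 100,
                    max_std_test = 0.2, pct_pre_filter = 0.05,
                    max_overlap = 0.5, max_cor = 0.5, tmd_len_ref = 20,
                    jmd_len = 10, ext_len = 4) {
  parts_tbl <- derive_parts(data, jmd_len = jmd_len, ext_len = ext_len)
  test_ids <- parts_tbl$id[parts_tbl$label == test_label]
  ref_ids <- parts_tbl$id[parts_tbl$label %in% ref_labels]
  if (length(test_ids) == 0 || length(ref_ids) == 0) {
    abort("both the test and the reference group must be non-empty")
  }
  space <- cpp_feature_space(parts, splits, scales)
  X <- cpp_feature_matrix(parts_tbl, parts, splits, scales)
  pre <- cpp_prefilter(space, X, test_ids, ref_ids,
                       max_std_test = max_std_test,
                       pct_pre_filter = pct_pre_filter)
  ranked <- cpp_rank(pre, X, test_ids, ref_ids) |>
    left_join(select(scales, "scale_id", "category", "subcategory"),
              by = "scale_id") |>
    feature_positions(splits = splits, tmd_len_ref = tmd_len_ref,
                      jmd_len = jmd_len, ext_len = ext_len)
  final <- cpp_redundancy_filter(ranked, scales, n_filter = n_filter,
                                 max_overlap = max_overlap, max_cor = max_cor)
  structure(
    list(
      features = final,
      matrix = X[, final$feature_id, drop = FALSE],
      labels = setNames(parts_tbl$label, parts_tbl$id),
      test_ids = test_ids,
      ref_ids = ref_ids,
      n_created = nrow(space),
      n_prefiltered = nrow(pre),
      config = list(
        parts = parts, n_filter = n_filter, max_std_test = max_std_test,
        pct_pre_filter = pct_pre_filter, max_overlap = max_overlap,
        max_cor = max_cor, tmd_len_ref = tmd_len_ref, jmd_len = jmd_len,
        ext_len = ext_len, test_label = test_label, ref_labels = ref_labels
      )
    ),
    class = "cpp_result"
  )
}

#' @export
print.cpp_result <- function(x, ...) {
  cat("<cpp_result>\n")
  cat("  created:     ", x$n_created, " features\n", sep = "")
  cat("  pre-filtered:", x$n_prefiltered, "features\n")
  cat("  accepted:    ", nrow(x$features), " features (n_filter = ",
      x$config$n_filter, ")\n", sep = "")
  cat("  comparison:  ", length(x$test_ids), "test vs", length(x$ref_ids),
      "reference proteins\n")
  invisible(x)
}

#' Positional aggregation of feature importance
#'
#' Projects a feature set onto the reference positional frame: each
#' feature's importance is divided equally among its positions, and
#' per-position sums form the profile (total importance is conserved). The
#' feature map aggregates the mean difference and importance per scale
#' subcategory and position.
#'
#' @param features Feature tibble with `positions`, `mean_dif`,
#'   `subcategory`, and an importance column.
#' @param importance Name of the importance column (default
#'   `"importance"`); if absent, equal importance 1 per feature is used.
#' @param jmd_len,tmd_len_ref Frame geometry (defaults 10 and 20, a
#'   40-position frame).
#' @return A list with `profile` (tibble: `position`, `region`,
#'   `importance`) and `feature_map` (tibble: `subcategory`, `position`,
#'   `mean_dif`, `importance`).
#' @export
positional_aggregation <- function(features, importance = "importance",
                                   jmd_len = 10, tmd_len_ref = 20) {
  n_pos <- 2 * jmd_len + tmd_len_ref
  imp <- if (importance %in% names(features)) features[[importance]] else
    rep(1, nrow(features))
  long <- tibble(
    subcategory = rep(features$subcategory, lengths(features$positions)),
    mean_dif = rep(features$mean_dif, lengths(features$positions)),
    imp_share = rep(imp / pmax(lengths(features$positions), 1),
                    lengths(features$positions)),
    position = unlist(features$positions)
  )
  profile <- long |>
    group_by(.data$position) |>
    summarise(importance = sum(.data$imp_share), .groups = "drop") |>
    tidyr::complete(position = seq_len(n_pos),
                    fill = list(importance = 0)) |>
    mutate(region = dplyr::case_when(
      .data$position <= jmd_len ~ "jmd_n",
      .data$position <= jmd_len + tmd_len_ref ~ "tmd",
      TRUE ~ "jmd_c"
    ))
  feature_map <- long |>
    group_by(.data$subcategory, .data$position) |>
    summarise(mean_dif = mean(.data$mean_dif),
              importance = sum(.data$imp_share), .groups = "drop")
  list(profile = profile, feature_map = feature_map)
}

#' @describeIn cpp_run Tidy the accepted feature table (positions flattened
#'   to a comma-separated string).
#' @param x A `cpp_result`.
#' @param ... Unused.
#' @export
tidy.cpp_result <- function(x, ...) {
  x$features |>
    mutate(positions = map_chr(.data$positions,
                               ~ paste(.x, collapse = ","))) |>
    as_tibble()
}

#' @describeIn cpp_run One-row summary of the run.
#' @export
glance.cpp_result <- function(x, ...) {
  tibble(
    n_created = x$n_created,
    n_prefiltered = x$n_prefiltered,
    n_accepted = nrow(x$features),
    n_test = length(x$test_ids),
    n_ref = length(x$ref_ids),
    top_abs_auc = max(abs(x$features$adjusted_auc))
  )
}
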