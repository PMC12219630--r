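#' Number of negatives needed to balance a PU dataset
#'
#' How many reliable negatives must be identified from the unlabeled pool so
#' that the negative class matches the positive class in size, e.g. 63
#' positives against 14 known negatives require 49 additional negatives.
#'
#' @param n_pos Number of positive samples.
#' @param n_neg_known Number of already-known negative samples.
#' @return `n_pos - n_neg_known`.
#' @export
pu_balance_quota <- function(n_pos, n_neg_known) {
  if (n_neg_known > n_pos) {
    abort("more known negatives than positives; nothing to identify")
  }
  if (n_neg_known < 0) abort("n_neg_known must be >= 0")
  as.integer(n_pos - n_neg_known)
}

# largest-remainder apportionment; earlier entries win remainder ties
largest_remainder <- function(ratios, total) {
  if (total == 0) return(integer(length(ratios)))
  ratios <- ratios / sum(ratios)
  raw <- ratios * total
  base <- floor(raw)
  left <- total - sum(base)
  if (left > 0) {
    ord <- order(-(raw - base), seq_along(raw)) # remainder desc, index asc
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Deterministic positive-unlabeled negative identification (dPULearn)
#'
#' Compresses the feature space with principal component analysis and, for
#' each retained component in order of explained variance, selects the
#' unlabeled samples farthest (in absolute 1-D distance on that component)
#' from the mean coordinate of the positive samples. Per-component quotas
#' are proportional to the explained-variance ratios of the retained
#' components (largest-remainder rounding; earlier components win remainder
#' ties); sample-id order breaks distance ties. The procedure contains no
#' randomness, so reruns are reproducible byte-for-byte.
#'
#' @param X Numeric feature matrix with sample ids as row names (typically a
#'   CPP feature matrix). `NA` cells are replaced by the column mean before
#'   PCA.
#' @param labels Named character vector (or factor) over the rows of `X`
#'   with values `"positive"`, `"negative"`, `"unlabeled"`.
#' @param n_needed Number of negatives to identify; `"auto"` balances the
#'   classes via [pu_balance_quota()].
#' @param n_components Either an integer count of components to retain, or
#'   a fraction in (0, 1): the smallest count whose cumulative explained
#'   variance reaches it (default 0.8).
#' @param standardize Z-standardize columns before PCA (default `TRUE`);
#'   with it on, the selection is invariant to positive rescaling of any
#'   feature column.
#' @return An object of class `pu_result`: list with `selected_ids` (in
#'   selection order), `per_pc_quota`, `pc_stats` (tibble: component,
#'   explained-variance ratio, positive-class mean), and the call
#'   parameters. [tidy()] returns the per-selection table.
#' @export
dpulearn <- function(X, labels, n_needed = "auto", n_components = 0.8,
                     standardize = TRUE) {
  if (is.null(rownames(X))) abort("X must have sample ids as row names")
  labels <- labels[rownames(X)]
  if (anyNA(labels)) abort("labels must cover every row of X")
  pos_ids <- rownames(X)[labels == "positive"]
  unl_ids <- rownames(X)[labels == "unlabeled"]
  if (length(pos_ids) < 2) abort("need at least 2 positive samples")
  if (identical(n_needed, "auto")) {
    n_needed <- pu_balance_quota(length(pos_ids), sum(labels == "negative"))
  }
  if (n_needed > length(unl_ids)) {
    abort(paste0("unlabeled pool (", length(unl_ids),
                 ") smaller than requested selection (", n_needed, ")"))
  }

  M <- X
  col_mean <- colMeans(M, na.rm = TRUE)
  for (j in which(apply(M, 2, anyNA))) {
    M[is.na(M[, j]), j] <- col_mean[j]
  }
  if (standardize) {
    sds <- apply(M, 2, sd)
    keep <- sds > 0
    M <- scale(M[, keep, drop = FALSE])
  }
  pca <- prcomp(M, center = !standardize, scale. = FALSE)
  ev_ratio <- pca$sdev^2 / sum(pca$sdev^2)

  m <- if (n_components >= 1) {
    min(as.integer(n_components), length(ev_ratio))
  } else {
    which(cumsum(ev_ratio) >= n_components)[1]
  }
  quota <- largest_remainder(ev_ratio[seq_len(m)], n_needed)

  scores <- pca$x
  pos_mean <- colMeans(scores[pos_ids, seq_len(m), drop = FALSE])
  selected <- character(0)
  sel_tbl <- list()
  for (pc in seq_len(m)) {
    if (quota[pc] == 0) next
    pool <- setdiff(unl_ids, selected)
    dist <- setNames(abs(scores[pool, pc] - pos_mean[pc]), pool)
    ord <- pool[order(-dist, pool)]
    take <- ord[seq_len(quota[pc])]
    selected <- c(selected, take)
    sel_tbl[[pc]] <- tibble(id = take, component = pc,
                            distance = dist[take])
  }
  structure(
    list(
      selected_ids = selected,
      per_pc_quota = quota,
      pc_stats = tibble(component = seq_len(m),
                        explained_variance = ev_ratio[seq_len(m)],
                        positive_mean = pos_mean),
      selection = bind_rows(sel_tbl),
      n_needed = n_needed,
      n_components = m,
      standardize = standardize
    ),
    class = "pu_result"
  )
}

#' @export
print.pu_result <- function(x, ...) {
  cat("<pu_result>\n")
  cat("  selected:", length(x$selected_ids), "reliable negatives\n")
  cat("  components:", x$n_components,
      sprintf("(quotas: %s)\n", paste(x$per_pc_quota, collapse = ", ")))
  invisible(x)
}

#' @describeIn dpulearn Per-selection table (id, component, distance).
#' @param x A `pu_result`.
#' @param ... Unused.
#' @export
tidy.pu_result <- function(x, ...) x$selection

#' @describeIn dpulearn One-row summary.
#' @export
glance.pu_result <- function(x, ...) {
  tibble(n_selected = length(x$selected_ids),
         n_components = x$n_components,
         variance_covered = sum(x$pc_stats$explained_variance))
}

#' Benchmark dPULearn against random negative sampling
#'
#' Compares the quality of the negatives each method selects: a seeded
#' evaluation subset of the unlabeled pool is reserved up front (identical
#' for every method), a downstream nearest-neighbour classifier is trained
#' on the positives against (a) the dPULearn-selected negatives and (b)
#' repeated uniform random draws from the remaining pool, and balanced
#' accuracy is measured on the reserved samples' ground-truth classes. A
#' nearest-neighbour learner is maximally sensitive to mislabeled training
#' samples, so the benchmark directly measures the purity of each
#' negative set (hidden positives drawn as "negatives" poison their
#' neighbourhoods). Because dPULearn is
#' column has zero variance; the random baseline is summarized as mean and
#' standard deviation, with a two-sided one-sample t-test of the random
#' draws against the dPULearn point value.
#'
#' @param X Feature matrix with sample ids as row names.
#' @param labels Named label vector (see [dpulearn()]).
#' @param truth Named vector of true classes (`"positive"`/`"negative"`)
#'   used only for evaluation, e.g. from the synthetic ground truth.
#' @param n_needed Negatives to select per method (`"auto"` balances).
#' @param n_repeats Random-baseline repeats (default 20).
#' @param eval_frac Fraction of the unlabeled pool reserved for evaluation
#'   (default 0.3).
#' @param seed Seed for the evaluation split and the random draws.
#' @param ... Passed to [dpulearn()].
#' @return A list with `dpulearn_ba`, `random_ba` (vector), `p_value`, and
#'   the tidy comparison tibble `summary`.
#' @export
pu_benchmark <- function(X, labels, truth, n_needed = "auto", n_repeats = 20,
                         eval_frac = 0.3, seed = 1, ...) {
  labels <- labels[rownames(X)]
  pos_ids <- rownames(X)[labels == "positive"]
  unl_ids <- rownames(X)[labels == "unlabeled"]
  if (identical(n_needed, "auto")) {
    n_needed <- pu_balance_quota(length(pos_ids), sum(labels == "negative"))
  }
  neg_known <- rownames(X)[labels == "negative"]

  set.seed(seed)
  eval_ids <- sort(sample(unl_ids, round(eval_frac * length(unl_ids))))
  pool_labels <- labels
  pool_labels[eval_ids] <- "held_out" # invisible to either selector

  Xi <- impute_na(X)
  eval_selection <- function(neg_ids) {
    train_ids <- c(pos_ids, neg_known, neg_ids)
    y <- train_ids %in% pos_ids
    d2 <- outer(rowSums(Xi[eval_ids, , drop = FALSE]^2),
                rowSums(Xi[train_ids, , drop = FALSE]^2), `+`) -
      2 * Xi[eval_ids, , drop = FALSE] %*% t(Xi[train_ids, , drop = FALSE])
    pred <- y[apply(d2, 1, which.min)]
    balanced_accuracy(truth[eval_ids] == "positive", pred)
  }

  dp <- dpulearn(X, pool_labels, n_needed = n_needed, ...)
  dp_ba <- eval_selection(dp$selected_ids)
  pool_ids <- setdiff(unl_ids, eval_ids)
  random_ba <- vapply(seq_len(n_repeats), function(r) {
    set.seed(seed + r)
    eval_selection(sample(pool_ids, n_needed))
  }, numeric(1))
  p_value <- if (sd(random_ba) == 0) {
    # degenerate baseline (e.g. every draw separates perfectly)
    if (isTRUE(all.equal(mean(random_ba), dp_ba))) 1 else 0
  } else {
    t.test(random_ba, mu = dp_ba, alternative = "two.sided")$p.value
  }
  list(
    dpulearn_ba = dp_ba,
    random_ba = random_ba,
    p_value = p_value,
    summary = tibble(
      method = c("dpulearn", "random"),
      mean_ba = c(dp_ba, mean(random_ba)),
      sd_ba = c(0, sd(random_ba))
    )
  )
}

# column-mean NA imputation used where a model cannot take NA cells
impute_na <- function(M) {
  cm <- colMeans(M, na.rm = TRUE)
  cm[is.nan(cm)] <- 0
  for (j in which(apply(M, 2, anyNA))) M[is.na(M[, j]), j] <- cm[j]
  M
}

balanced_accuracy <- function(truth, pred) {
  sens <- mean(pred[truth])
  spec <- mean(!pred[!truth])
  (sens + spec) / 2
}
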