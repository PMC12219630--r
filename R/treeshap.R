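# Path-dependent TreeSHAP over a unified tree representation.
#
# A tree is a list of parallel vectors indexed by node (1-based):
#   feature : integer column index of the split variable (NA at leaves)
#   split   : numeric threshold
#   yes/no  : child node indices (left = condition true); NA at leaves
#   lt      : TRUE -> go left when x <  split; FALSE -> left when x <= split
#   cover   : training-sample count (or weight) reaching the node
#   value   : leaf output (NA at internal nodes)
#
# Model ensembles combine per-tree attributions linearly: averaging for
# forests/CART, summation (plus intercept) for boosted trees.

tree_left <- function(tree, node, xval) {
  if (tree$lt[node]) xval < tree$split[node] else xval <= tree$split[node]
}

# evaluate one tree on one sample
eval_tree <- function(tree, x) {
  node <- 1L
  while (!is.na(tree$feature[node])) {
    node <- if (tree_left(tree, node, x[tree$feature[node]]))
      tree$yes[node] else tree$no[node]
  }
  tree$value[node]
}

# cover-weighted expectation of a tree's output
tree_expectation <- function(tree) {
  leaves <- which(is.na(tree$feature))
  sum(tree$value[leaves] * tree$cover[leaves]) / tree$cover[1]
}

# Lundberg's polynomial-time path-dependent algorithm for one tree/sample.
# The path state is a matrix with columns d (feature), z (zero fraction),
# o (one fraction), w (weight); R's copy-on-modify gives each branch its
# own path copy for free.
shap_tree <- function(tree, x, n_features) {
  phi <- numeric(n_features)

  extend <- function(m, pz, po, pd) {
    l <- nrow(m)
    m <- rbind(m, c(pd, pz, po, if (l == 0) 1 else 0))
    if (l > 0) {
      for (i in l:1) {
        m[i + 1, 4] <- m[i + 1, 4] + po * m[i, 4] * i / (l + 1)
        m[i, 4] <- pz * m[i, 4] * (l + 1 - i) / (l + 1)
      }
    }
    m
  }

  unwind <- function(m, i) {
    l <- nrow(m)
    n <- m[l, 4]
    o_i <- m[i, 3]
    z_i <- m[i, 2]
    if (l > 1) {
      for (j in (l - 1):1) {
        if (o_i != 0) {
          t <- m[j, 4]
          m[j, 4] <- n * l / (j * o_i)
          n <- t - m[j, 4] * z_i * (l - j) / l
        } else {
          m[j, 4] <- m[j, 4] * l / (z_i * (l - j))
        }
      }
    }
    if (i < l) m[i:(l - 1), 1:3] <- m[(i + 1):l, 1:3, drop = FALSE]
    m[-l, , drop = FALSE]
  }

  # sum of weights after unwinding element i, without materializing
  unwound_sum <- function(m, i) {
    l <- nrow(m)
    o_i <- m[i, 3]
    z_i <- m[i, 2]
    total <- 0
    n <- m[l, 4]
    if (l > 1) {
      for (j in (l - 1):1) {
        if (o_i != 0) {
          t <- n * l / (j * o_i)
          total <- total + t
          n <- m[j, 4] - t * z_i * (l - j) / l
        } else {
          total <- total + m[j, 4] * l / (z_i * (l - j))
        }
      }
    } else {
      total <- 0
    }
    total
  }

  recurse <- function(node, m, pz, po, pd) {
    m <- extend(m, pz, po, pd)
    if (is.na(tree$feature[node])) {
      l <- nrow(m)
      if (l > 1) {
        for (i in 2:l) {
          w <- unwound_sum(m, i)
          f <- m[i, 1]
          phi[f] <<- phi[f] + w * (m[i, 3] - m[i, 2]) * tree$value[node]
        }
      }
      return(invisible(NULL))
    }
    f <- tree$feature[node]
    left <- tree$yes[node]
    right <- tree$no[node]
    hot <- if (tree_left(tree, node, x[f])) left else right
    cold <- if (hot == left) right else left
    iz <- 1
    io <- 1
    k <- which(m[, 1] == f)
    if (length(k) > 0) {
      k <- k[1]
      iz <- m[k, 2]
      io <- m[k, 3]
      m <- unwind(m, k)
    }
    r_node <- tree$cover[node]
    recurse(hot, m, iz * tree$cover[hot] / r_node, io, f)
    recurse(cold, m, iz * tree$cover[cold] / r_node, 0, f)
    invisible(NULL)
  }

  m0 <- matrix(numeric(0), ncol = 4,
               dimnames = list(NULL, c("d", "z", "o", "w")))
  recurse(1L, m0, 1, 1, 0L)
  phi
}

# route rows of X down a tree, returning per-node reach counts
route_cover <- function(tree, X) {
  n_nodes <- length(tree$feature)
  cover <- numeric(n_nodes)
  assign_rows <- function(node, rows) {
    cover[node] <<- length(rows)
    if (is.na(tree$feature[node]) || length(rows) == 0) return(invisible(NULL))
    xv <- X[rows, tree$feature[node]]
    go_left <- if (tree$lt[node]) xv < tree$split[node] else xv <= tree$split[node]
    assign_rows(tree$yes[node], rows[go_left])
    assign_rows(tree$no[node], rows[!go_left])
    invisible(NULL)
  }
  assign_rows(1L, seq_len(nrow(X)))
  # empty branches get a vanishing but nonzero weight so ratios stay defined
  cover[cover == 0] <- 1e-9
  cover
}

new_tree <- function(feature, split, yes, no, lt, cover, value) {
  list(feature = as.integer(feature), split = as.numeric(split),
       yes = as.integer(yes), no = as.integer(no), lt = lt,
       cover = as.numeric(cover), value = as.numeric(value))
}

extract_trees_rpart <- function(fit, feature_names) {
  frame <- fit$frame
  node_no <- as.integer(rownames(frame))
  n <- nrow(frame)
  is_leaf <- frame$var == "<leaf>"
  feature <- rep(NA_integer_, n)
  split <- rep(NA_real_, n)
  yes <- no <- rep(NA_integer_, n)
  lt <- rep(TRUE, n)
  # primary split rows in fit$splits: one block per non-leaf frame row
  split_row <- 1L
  for (i in seq_len(n)) {
    if (is_leaf[i]) next
    srow <- fit$splits[split_row, ]
    split_row <- split_row + frame$ncompete[i] + frame$nsurrogate[i] + 1L
    feature[i] <- match(as.character(frame$var[i]), feature_names)
    split[i] <- srow[["index"]]
    left_child <- match(node_no[i] * 2L, node_no)
    right_child <- match(node_no[i] * 2L + 1L, node_no)
    if (srow[["ncat"]] < 0) {
      # x < split goes to the left child
      yes[i] <- left_child
      no[i] <- right_child
    } else {
      # x >= split goes to the left child; swap to keep "yes = condition"
      yes[i] <- right_child
      no[i] <- left_child
    }
  }
  value <- rep(NA_real_, n)
  value[is_leaf] <- frame$yval2[is_leaf, 5] # P(class == "1")
  list(trees = list(new_tree(feature, split, yes, no, lt, frame$n, value)),
       combine = "average", intercept = 0)
}

extract_trees_rf <- function(fit, X_train) {
  trees <- lapply(seq_len(fit$ntree), function(k) {
    tm <- randomForest::getTree(fit, k, labelVar = FALSE)
    is_leaf <- tm[, "status"] == -1
    tree <- new_tree(
      feature = ifelse(is_leaf, NA_integer_, tm[, "split var"]),
      split = tm[, "split point"],
      yes = ifelse(is_leaf, NA_integer_, tm[, "left daughter"]),
      no = ifelse(is_leaf, NA_integer_, tm[, "right daughter"]),
      lt = rep(FALSE, nrow(tm)), # x <= split point goes left
      cover = 1,
      # vote-fraction leaves: predicted class 2 (= "1") contributes 1
      value = ifelse(is_leaf, as.numeric(tm[, "prediction"] == 2), NA_real_)
    )
    tree$cover <- route_cover(tree, X_train)
    tree
  })
  list(trees = trees, combine = "average", intercept = 0)
}

extract_trees_ranger <- function(fit, X_train, feature_names) {
  pos_col <- NULL
  trees <- lapply(seq_len(fit$num.trees), function(k) {
    ti <- ranger::treeInfo(fit, k)
    if (is.null(pos_col)) {
      pos_col <<- grep("^pred\\.", names(ti), value = TRUE)
      pos_col <<- pos_col[endsWith(pos_col, ".1") | pos_col == "pred.1"][1]
    }
    is_leaf <- ti$terminal
    tree <- new_tree(
      feature = ifelse(is_leaf, NA_integer_,
                       match(ti$splitvarName, feature_names)),
      split = ti$splitval,
      yes = ti$leftChild + 1L,
      no = ti$rightChild + 1L,
      lt = rep(FALSE, nrow(ti)), # x <= splitval goes left
      cover = 1,
      value = ifelse(is_leaf, ti[[pos_col]], NA_real_)
    )
    tree$cover <- route_cover(tree, X_train)
    tree
  })
  list(trees = trees, combine = "average", intercept = 0)
}

extract_trees_xgb <- function(fit, feature_names) {
  dt <- as.data.frame(xgboost::xgb.model.dt.tree(model = fit))
  value_col <- if ("Gain" %in% names(dt)) "Gain" else "Quality"
  base_score <- 0.5 # xgboost default; margin intercept for squared error
  trees <- lapply(split(dt, dt$Tree), function(td) {
    td <- td[order(td$Node), , drop = FALSE]
    is_leaf <- td$Feature == "Leaf"
    id_map <- setNames(seq_len(nrow(td)), td$ID)
    yes <- unname(id_map[as.character(td$Yes)])
    no <- unname(id_map[as.character(td$No)])
    new_tree(
      feature = ifelse(is_leaf, NA_integer_,
                       match(td$Feature, feature_names)),
      # the model dump prints 9 significant digits: snapping back to the
      # nearest float32 recovers the stored threshold exactly
      split = as_float32(suppressWarnings(as.numeric(td$Split))),
      yes = ifelse(is_leaf, NA_integer_, yes),
      no = ifelse(is_leaf, NA_integer_, no),
      lt = rep(TRUE, nrow(td)), # x < Split goes to Yes
      cover = td$Cover,
      value = ifelse(is_leaf, td[[value_col]], NA_real_)
    )
  })
  # xgboost stores features in single precision; mark for comparison
  list(trees = unname(trees), combine = "sum", intercept = base_score,
       f32 = TRUE)
}

# round a double vector to float32 precision (xgboost's internal storage)
as_float32 <- function(v) {
  readBin(writeBin(as.numeric(v), raw(), size = 4L), "numeric",
          size = 4L, n = length(v))
}

#' Extract a unified tree ensemble from a fitted tree model
#'
#' Converts a fitted CART (`rpart`), random forest (`randomForest`),
#' extremely randomized trees (`ranger` probability forest), or gradient
#' boosting (`xgboost`) model into the package's unified tree table, used
#' by [tree_shap()]. Forest node covers are obtained by routing the
#' training matrix down each tree.
#'
#' @param model_id One of the registry's tree-based model ids.
#' @param fit The fitted model object.
#' @param X_train Training matrix (needed for forest covers).
#' @param feature_names Column names the trees' split variables refer to.
#' @return A list with `trees`, `combine` (`"average"` or `"sum"`), and
#'   `intercept`.
#' @export
extract_trees <- function(model_id, fit, X_train, feature_names) {
  switch(model_id,
    cart = extract_trees_rpart(fit, feature_names),
    random_forest = ,
    bagged_trees = extract_trees_rf(fit, X_train),
    extra_trees = extract_trees_ranger(fit, X_train, feature_names),
    gradient_boosting = extract_trees_xgb(fit, feature_names),
    abort(paste0("not a tree-based model: ", model_id))
  )
}

#' Tree-SHAP attributions for a tree ensemble
#'
#' Computes per-feature SHAP values for each row of `X` with the
#' path-dependent TreeSHAP algorithm, using training-cover weights as the
#' background distribution. Additivity holds exactly per model: the base
#' value plus the row's SHAP values equals the ensemble's output for that
#' row.
#'
#' @param ensemble A unified ensemble from [extract_trees()].
#' @param X Numeric matrix of samples to explain (columns in the trees'
#'   feature order).
#' @return A list with `shap` (matrix, same shape as `X`), `base` (scalar
#'   expected output), and `prediction` (ensemble output per row).
#' @export
tree_shap <- function(ensemble, X) {
  n <- nrow(X)
  p <- ncol(X)
  shap <- matrix(0, nrow = n, ncol = p, dimnames = dimnames(X))
  pred <- numeric(n)
  n_trees <- length(ensemble$trees)
  denom <- if (ensemble$combine == "average") n_trees else 1
  base <- ensemble$intercept +
    sum(vapply(ensemble$trees, tree_expectation, numeric(1))) / denom
  for (i in seq_len(n)) {
    x <- X[i, ]
    if (isTRUE(ensemble$f32)) x <- as_float32(x)
    acc <- numeric(p)
    out <- 0
    for (tree in ensemble$trees) {
      acc <- acc + shap_tree(tree, x, p)
      out <- out + eval_tree(tree, x)
    }
    shap[i, ] <- acc / denom
    pred[i] <- ensemble$intercept + out / denom
  }
  list(shap = shap, base = base, prediction = setNames(pred, rownames(X)))
}
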