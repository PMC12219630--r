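test_that("the feature space is the ordered part x split x scale product", {
  sc <- toy_scales()
  sp <- cpp_splits()
  expect_equal(nrow(cpp_feature_space("tmd", sp[1, ], sc[1, ])), 1)
  expect_equal(nrow(cpp_feature_space(c("tmd", "jmd_n"), sp[1:5, ],
                                      sc[c(1, 2, 3, 1), ])), 40)
  space <- cpp_feature_space(c("tmd", "jmd_n"), sp[1:2, ], sc)
  # part-major, then split, then scale
  expect_equal(space$part, rep(c("tmd", "jmd_n"), each = 6))
  expect_equal(space$split_id[1:6], rep(1:2, each = 3))
})

test_that("feature matrix cells are hand-computable means, NA when inapplicable", {
  data <- toy_proteins()[1:2, ]
  parts_tbl <- derive_parts(data)
  sc <- toy_scales()
  sp <- cpp_splits()
  X <- cpp_feature_matrix(parts_tbl, parts = c("tmd", "tmd_c_jmd_c"),
                          splits = sp, scales = sc)
  expect_equal(ncol(X), 2 * 330 * 3)
  expect_true(all(X >= 0 & X <= 1, na.rm = TRUE))

  # P1: TMD is poly-L; whole-part segment under any scale scoring L as 0
  expect_equal(unname(X["P1", "tmd|1|SC_CHARGE"]), 0)
  # P1 tmd_c_jmd_c = "LLLLLLLLLL" + "KKKQTTTTTT": segment 2 of 2 is the JMD-C
  # -> charge scale mean = 3 K of 10
  expect_equal(unname(X["P1", "tmd_c_jmd_c|3|SC_CHARGE"]), 0.3)
  # branch scale on the same JMD-C: 6 T of 10
  expect_equal(unname(X["P1", "tmd_c_jmd_c|3|SC_BRANCH"]), 0.6)

  # a 15-segment split of a 10-residue part leaves empty segments -> NA
  seg15 <- sp$split_id[sp$kind == "segment" & sp$n_split == 15 &
                         sp$i_split == 2]
  p2_len <- nchar(parts_tbl$tmd_c_jmd_c[parts_tbl$id == "P2"])
  expect_true(p2_len == 20) # sanity: applicable there
  # determinism: identical reruns
  X2 <- cpp_feature_matrix(parts_tbl, parts = c("tmd", "tmd_c_jmd_c"),
                           splits = sp, scales = sc)
  expect_identical(X, X2)
})

test_that("adjusted AUC matches a brute-force concordance oracle", {
  brute <- function(test, ref) {
    conc <- outer(test, ref, function(a, b) (a > b) + 0.5 * (a == b))
    mean(conc) - 0.5
  }
  expect_equal(adjusted_auc(c(0.9, 0.8, 0.7), c(0.3, 0.2, 0.1)), 0.5)
  expect_equal(adjusted_auc(c(1, 3), c(2, 4)), -0.25)
  expect_equal(adjusted_auc(c(1, 2, 3), c(1, 2, 3)), 0)

  set.seed(42)
  for (i in 1:200) {
    n1 <- sample(1:8, 1)
    n2 <- sample(1:8, 1)
    # discrete values force ties regularly
    test <- sample(seq(0, 1, by = 0.25), n1, replace = TRUE)
    ref <- sample(seq(0, 1, by = 0.25), n2, replace = TRUE)
    expect_equal(adjusted_auc(test, ref), brute(test, ref),
                 tolerance = 1e-12)
    expect_equal(adjusted_auc(test, ref), -adjusted_auc(ref, test),
                 tolerance = 1e-12)
    expect_true(abs(adjusted_auc(test, ref)) <= 0.5)
  }
})

test_that("pre-filter drops high-dispersion features then cuts by |mean diff|", {
  set.seed(3)
  n_feat <- 200
  ids <- c(sprintf("t%02d", 1:10), sprintf("r%02d", 1:10))
  X <- matrix(runif(20 * n_feat, 0.45, 0.55), nrow = 20,
              dimnames = list(ids, sprintf("F%03d", 1:n_feat)))
  space <- tibble::tibble(feature_id = colnames(X))
  test_ids <- ids[1:10]
  ref_ids <- ids[11:20]

  # all features pass the std filter: floor(0.05 * 200) = 10 kept
  kept <- cpp_prefilter(space, X, test_ids, ref_ids,
                        max_std_test = 0.2, pct_pre_filter = 0.05)
  expect_equal(nrow(kept), 10)
  stats_all <- abs(colMeans(X[test_ids, ]) - colMeans(X[ref_ids, ]))
  expect_setequal(kept$feature_id,
                  names(sort(stats_all, decreasing = TRUE))[1:10])

  # a feature with test std above the threshold is dropped regardless
  X2 <- X
  X2[test_ids, "F001"] <- rep(c(0, 1), 5) # std ~0.53, huge mean diff
  kept2 <- cpp_prefilter(space, X2, test_ids, ref_ids)
  expect_false("F001" %in% kept2$feature_id)

  expect_warning(
    cpp_prefilter(space[1:20, ], X2[, 1:20], test_ids, ref_ids,
                  max_std_test = 1e-6),
    "pass the std filter"
  )
})

test_that("ranking orders by |AUC| with |mean diff| and id as tie-breaks", {
  feats <- tibble::tibble(
    feature_id = c("a", "b", "c", "d"),
    mean_dif = c(0.1, 0.2, 0.1, 0.3)
  )
  X <- matrix(
    c(0.9, 0.8, 0.1, 0.2,   # a: AUC +0.5
      0.1, 0.2, 0.9, 0.8,   # b: AUC -0.5
      0.5, 0.5, 0.5, 0.5,   # c: AUC 0
      0.6, 0.4, 0.5, 0.5),  # d: mixed
    nrow = 4,
    dimnames = list(c("t1", "t2", "r1", "r2"), c("a", "b", "c", "d"))
  )
  ranked <- cpp_rank(feats, X, c("t1", "t2"), c("r1", "r2"))
  # |−0.5| ties |+0.5|; mean_dif 0.2 beats 0.1
  expect_equal(ranked$feature_id[1:2], c("b", "a"))
  expect_equal(ranked$feature_id[4], "c")
})

test_that("redundancy filtering is greedy with a prefix property", {
  sc <- toy_scales()
  base <- tibble::tibble(
    feature_id = c("f1", "f2", "f3", "f4"),
    scale_id = c("SC_CHARGE", "SC_CHARGE", "SC_CHARGE", "SC_SMALL"),
    subcategory = c("charge", "charge", "charge", "size"),
    adjusted_auc = c(0.5, 0.45, 0.4, 0.35),
    mean_dif = c(0.5, 0.45, 0.4, 0.35),
    positions = list(c(1L, 2L, 3L, 4L), c(1L, 2L, 3L, 4L), c(11L, 12L),
                     c(1L, 2L, 3L))
  )
  out <- cpp_redundancy_filter(base, sc, n_filter = 10)
  # exact positional duplicate of an accepted same-subcategory feature: out
  expect_false("f2" %in% out$feature_id)
  # same scale but disjoint positions: accepted
  expect_true("f3" %in% out$feature_id)
  # overlapping positions but uncorrelated scale, different subcategory: kept
  expect_true("f4" %in% out$feature_id)

  # n_filter truncates in rank order and is a prefix of larger runs
  fx <- small_cpp()
  parts_tbl <- derive_parts(fx$sim$data)
  X <- cpp_feature_matrix(parts_tbl, scales = fx$scales)
  space <- cpp_feature_space(cpp_default_parts(), cpp_splits(), fx$scales)
  ranked <- cpp_prefilter(space, X, fx$res$test_ids, fx$res$ref_ids) |>
    cpp_rank(X, fx$res$test_ids, fx$res$ref_ids) |>
    dplyr::left_join(dplyr::select(fx$scales, "scale_id", "subcategory"),
                     by = "scale_id") |>
    feature_positions()
  small <- cpp_redundancy_filter(ranked, fx$scales, n_filter = 10)
  large <- cpp_redundancy_filter(ranked, fx$scales, n_filter = 25)
  expect_equal(nrow(small), 10)
  expect_equal(large$feature_id[1:10], small$feature_id)
})

test_that("the full CPP run is deterministic and recovers the planted signal", {
  fx <- small_cpp()
  res <- fx$res
  expect_lte(nrow(res$features), 40)
  expect_equal(res$n_created, 3 * 330 * nrow(fx$scales))

  rerun <- cpp_run(fx$sim$data, fx$scales, n_filter = 40,
                   ref_labels = "negative")
  expect_identical(tidy(res), tidy(rerun))
  expect_identical(res$matrix, rerun$matrix)

  # the top feature points into a planted region
  planted <- unlist(purrr::map2(fx$sim$truth$regions$start,
                                fx$sim$truth$regions$stop, seq))
  expect_true(any(res$features$positions[[1]] %in% planted))
  expect_gte(truth_report(fx$sim$truth, cpp = res)$positional_recall, 0.6)
})

test_that("positional aggregation conserves importance", {
  feats <- tibble::tibble(
    feature_id = c("a", "b", "c"),
    subcategory = c("s1", "s1", "s2"),
    mean_dif = c(0.4, -0.2, 0.1),
    importance = c(1, 0.5, 0.25),
    positions = list(c(1L, 2L, 3L, 4L), c(3L, 4L), 7L)
  )
  agg <- positional_aggregation(feats)
  expect_equal(sum(agg$profile$importance), 1.75, tolerance = 1e-9)
  # one feature with importance 1 over 4 positions: 0.25 each
  expect_equal(agg$profile$importance[1:2], c(0.25, 0.25))
  # position 3 takes shares from a (1/4) and b (0.5/2)
  expect_equal(agg$profile$importance[3], 0.25 + 0.25)
  expect_equal(nrow(agg$profile), 40)
  fm <- agg$feature_map
  expect_equal(fm$mean_dif[fm$subcategory == "s1" & fm$position == 3],
               mean(c(0.4, -0.2)))
  expect_equal(fm$importance[fm$subcategory == "s2" & fm$position == 7], 0.25)
})
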