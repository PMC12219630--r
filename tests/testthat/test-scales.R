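make_scale_row <- function(id, values, subcat = "s1") {
  stopifnot(length(values) == 20)
  tibble::as_tibble(c(list(scale_id = id),
                      stats::setNames(as.list(values), aa_alphabet()),
                      list(category = "c", subcategory = subcat)))
}

test_that("normalization maps to [0,1] and rejects unusable scales", {
  set.seed(8)
  raw_vals <- c(2, 4.5, 7, runif(17, 2.1, 6.9))
  raw <- dplyr::bind_rows(
    make_scale_row("main", raw_vals),
    make_scale_row("const", rep(3, 20)),
    make_scale_row("dup_a", (1:20)^2),
    make_scale_row("dup_b", (1:20)^2),
    make_scale_row("gap", c(NA, runif(19)))
  )
  expect_message(out <- normalize_scales(raw), "dropped")
  expect_setequal(out$scale_id, c("main", "dup_a"))
  vals <- as.matrix(out[, aa_alphabet()])
  expect_equal(unname(apply(vals, 1, min)), c(0, 0))
  expect_equal(unname(apply(vals, 1, max)), c(1, 1))

  # the raw value 4.5 on a 2..7 scale lands at (4.5 - 2) / 5 = 0.5
  main <- out[out$scale_id == "main", ]
  expect_equal(unname(unlist(main[, aa_alphabet()])[2]), 0.5)

  # idempotent on the numeric content
  renorm <- normalize_scales(out)
  expect_equal(as.matrix(renorm[, aa_alphabet()]), vals)
  expect_equal(renorm$scale_id, out$scale_id)
})

test_that("feature values are means of scale values at selected residues", {
  sc <- toy_scales()
  small <- sc[sc$scale_id == "SC_SMALL", ]
  expect_equal(feature_value("GL", 1:2, small), 0.5)
  expect_equal(feature_value("GL", 2, small), 0)
  expect_equal(feature_value("AKK", 1:3, sc[sc$scale_id == "SC_CHARGE", ]),
               2 / 3)
  # permutation invariance and bounds
  expect_equal(feature_value("AKKG", c(3, 1, 2), small),
               feature_value("AKKG", 1:3, small))
  expect_true(is.na(feature_value("AKK", NULL, small)))
  expect_error(feature_value("AKK", 4, small), "out of range")
})

test_that("scale selection covers every subcategory with cluster medoids", {
  set.seed(5)
  base <- matrix(runif(5 * 20), nrow = 5)
  rows <- list()
  for (i in 1:5) {
    rows[[i]] <- make_scale_row(sprintf("base%02d", i), base[i, ],
                                subcat = paste0("s", (i - 1) %% 3 + 1))
  }
  # two near-duplicate pairs (same subcategory as their source)
  rows[[6]] <- make_scale_row("copy01", base[1, ] + 1e-9, "s1")
  rows[[7]] <- make_scale_row("copy02", base[2, ] + 1e-9, "s2")
  for (i in 8:10) {
    rows[[i]] <- make_scale_row(sprintf("extra%02d", i), runif(20),
                                subcat = paste0("s", (i - 1) %% 3 + 1))
  }
  scales <- suppressMessages(normalize_scales(dplyr::bind_rows(rows)))

  sel <- aaclust_select(scales)
  expect_true(all(c("s1", "s2", "s3") %in% sel$subcategory))
  # a perfectly correlated pair collapses to one representative
  expect_false(all(c("base01", "copy01") %in% sel$scale_id))

  # brute force the smallest covering k on the same tree
  m <- t(as.matrix(scales[, aa_alphabet()]))
  colnames(m) <- scales$scale_id
  hc <- stats::hclust(stats::as.dist(1 - stats::cor(m)), method = "complete")
  expected_k <- NULL
  for (k in 3:nrow(scales)) {
    cl <- stats::cutree(hc, k = k)
    reps <- vapply(split(names(cl), cl), function(ids) {
      if (length(ids) == 1) return(ids)
      score <- rowMeans(stats::cor(m)[ids, ids])
      ids[order(-score, ids)][1]
    }, character(1))
    if (all(c("s1", "s2", "s3") %in%
              scales$subcategory[match(reps, scales$scale_id)])) {
      expected_k <- k
      break
    }
  }
  expect_equal(attr(sel, "k"), expected_k)

  # row order does not change the selection; ids break medoid ties
  shuffled <- scales[sample(nrow(scales)), ]
  expect_equal(aaclust_select(shuffled)$scale_id, sel$scale_id)

  # identical scales under different ids: the smaller id is the medoid
  one <- suppressMessages(normalize_scales(make_scale_row("zz", base[1, ], "s1")))
  twins <- dplyr::bind_rows(one, dplyr::mutate(one, scale_id = "aa"))
  sel2 <- aaclust_select(twins)
  expect_equal(sel2$scale_id, "aa")

  expect_error(aaclust_select(scales, subcategories = c("s1", "ghost")),
               "ghost")
})
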