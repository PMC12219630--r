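# Shared fixtures, built once per test run and memoised. All data are
# generated in code; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# a small annotated protein table with exactly 10-residue flanks
toy_proteins <- function() {
  tibble::tibble(
    id = c("P1", "P2", "P3"),
    sequence = c(
      paste0(strrep("S", 10), strrep("L", 20), "KKKQ", strrep("T", 6)),
      paste0(strrep("A", 10), strrep("V", 21), "RKSQ", strrep("G", 6)),
      paste0(strrep("G", 12), strrep("I", 20), strrep("E", 10))
    ),
    tmd_start = c(11L, 11L, 13L),
    tmd_stop = c(30L, 31L, 32L),
    label = c("positive", "negative", "unlabeled")
  )
}

# deterministic 3-scale set covering two subcategories
toy_scales <- function() {
  aa <- aa_alphabet()
  mk <- function(id, high, subcat) {
    v <- stats::setNames(rep(0, 20), aa)
    v[high] <- 1
    c(list(scale_id = id), as.list(v),
      list(category = "toy", subcategory = subcat))
  }
  tibble::as_tibble(dplyr::bind_rows(
    mk("SC_CHARGE", c("K", "R"), "charge"),
    mk("SC_SMALL", c("G", "A", "S"), "size"),
    mk("SC_BRANCH", c("V", "I", "T"), "branch")
  ))
}

# small planted-signature dataset + scales + CPP run, shared across files
small_cpp <- function() {
  fixture("small_cpp", function() {
    sim <- synth_dataset(n_pos = 20, n_neg = 20, n_unlabeled = 20,
                         effect = 1, seed = 11)
    scales <- synth_scaleset(12, 4, seed = 7)
    res <- cpp_run(sim$data, scales, n_filter = 40, ref_labels = "negative")
    list(sim = sim, scales = scales, res = res)
  })
}

# tiny trained ensemble on the small CPP matrix
small_bundle <- function() {
  fixture("small_bundle", function() {
    fx <- small_cpp()
    monte_carlo_train(fx$res$matrix, fx$res$labels, n_rounds = 2,
                      top_k_grid = c(10, 20), seed_base = 7)
  })
}
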