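# Background residue pools. TMD cores of single-span proteins are dominated
# by aliphatic/aromatic residues; juxtamembrane stretches are mixed.
TMD_BACKGROUND <- c(L = 0.30, I = 0.15, V = 0.15, F = 0.12, A = 0.10,
                    G = 0.05, M = 0.04, T = 0.03, S = 0.03, C = 0.03)
JMD_BACKGROUND <- c(S = 0.09, E = 0.08, K = 0.08, L = 0.08, R = 0.07,
                    T = 0.07, Q = 0.07, A = 0.07, P = 0.06, G = 0.06,
                    D = 0.06, N = 0.05, V = 0.05, I = 0.04, H = 0.04,
                    F = 0.03)

# planted positive-class signature: region -> residue pool
SIGNATURE_POOLS <- list(
  anchor = c("K", "R"),            # basic TMD-C anchor (first 4 of JMD-C)
  tmd_n = c("G", "A", "S"),        # small residues in the N-terminal half
  cleavage = c("V", "I", "T")      # beta-branched cleavage window (last 4 TMD)
)

sample_residues <- function(n, pool) {
  sample(names(pool), n, replace = TRUE, prob = pool)
}

#' Generate a synthetic membrane-protein dataset with a planted signature
#'
#' Emulates a positive/negative/unlabeled substrate-discrimination dataset
#' of single-span N-out proteins: every entry has a hydrophobic-core TMD of
#' length drawn from `tmd_len_range`, flanking juxtamembrane domains of
#' `jmd_len` residues drawn from a mixed composition, and short ectodomain /
#' cytosolic tails. Proteins carrying the positive-class signature
#' additionally replace, independently per position with probability
#' `effect`, the TMD-C anchor residues (first four of the JMD-C) by K/R, the
#' N-terminal TMD half by G/A/S, and the last four TMD residues (the
#' cleavage window) by V/I/T. At `effect = 0` the classes are statistically
#' indistinguishable; at `effect = 1` the planted regions are fully
#' determined. A fraction `unlabeled_pos_frac` of the unlabeled pool
#' carries the signature too (true positives hidden in the pool), making
#' the positive-unlabeled setting realistic.
#'
#' @param n_pos,n_neg,n_unlabeled Class sizes (defaults 63, 14, 631, the
#'   expert-substrate / known non-substrate / reference-pool sizes of a
#'   TMHMM-annotated substrate study).
#' @param effect Signature strength in `[0, 1]` (default 1).
#' @param tmd_len_range TMD lengths to draw from (default 19:25).
#' @param jmd_len Juxtamembrane length (default 10).
#' @param unlabeled_pos_frac Fraction of unlabeled entries that secretly
#'   carry the signature (default 0.2).
#' @param seed Random seed; the same seed reproduces the dataset exactly.
#' @return A list with `data` (protein tibble: `id`, `sequence`,
#'   `tmd_start`, `tmd_stop`, `label`) and `truth` (list: `true_class`
#'   named vector, `regions` tibble of planted reference-frame positions,
#'   `pools` the planted residue pools).
#' @export
synth_dataset <- function(n_pos = 63, n_neg = 14, n_unlabeled = 631,
                          effect = 1, tmd_len_range = 19:25, jmd_len = 10,
                          unlabeled_pos_frac = 0.2, seed = 1) {
  if (effect < 0 || effect > 1) abort("effect must be in [0, 1]")
  if (min(tmd_len_range) < 8) abort("TMD lengths below 8 are not supported")
  set.seed(seed)

  n <- n_pos + n_neg + n_unlabeled
  if (n == 0) abort("empty dataset requested")
  label <- c(rep("positive", n_pos), rep("negative", n_neg),
             rep("unlabeled", n_unlabeled))
  hidden_pos <- label == "unlabeled" &
    runif(n) < unlabeled_pos_frac
  signature <- label == "positive" | hidden_pos
  true_class <- ifelse(signature, "positive", "negative")

  make_one <- function(has_signature) {
    tmd_len <- sample(tmd_len_range, 1)
    n_half <- ceiling(tmd_len / 2)
    ecto_extra <- sample(0:20, 1)
    tail_extra <- sample(0:10, 1)
    tmd <- sample_residues(tmd_len, TMD_BACKGROUND)
    jmd_n <- sample_residues(jmd_len, JMD_BACKGROUND)
    jmd_c <- sample_residues(jmd_len, JMD_BACKGROUND)
    if (has_signature) {
      plant <- function(res, pool) {
        hit <- runif(length(res)) < effect
        res[hit] <- sample(pool, sum(hit), replace = TRUE)
        res
      }
      jmd_c[1:4] <- plant(jmd_c[1:4], SIGNATURE_POOLS$anchor)
      tmd[seq_len(n_half)] <- plant(tmd[seq_len(n_half)], SIGNATURE_POOLS$tmd_n)
      tmd[(tmd_len - 3):tmd_len] <- plant(tmd[(tmd_len - 3):tmd_len],
                                          SIGNATURE_POOLS$cleavage)
    }
    ecto <- sample_residues(ecto_extra, JMD_BACKGROUND)
    tail <- sample_residues(tail_extra, JMD_BACKGROUND)
    seq <- paste(c(ecto, jmd_n, tmd, jmd_c, tail), collapse = "")
    tibble(sequence = seq,
           tmd_start = ecto_extra + jmd_len + 1L,
           tmd_stop = ecto_extra + jmd_len + tmd_len)
  }

  rows <- bind_rows(lapply(signature, make_one))
  data <- tibble(
    id = sprintf("SYN%04d", seq_len(n)),
    sequence = rows$sequence,
    tmd_start = as.integer(rows$tmd_start),
    tmd_stop = as.integer(rows$tmd_stop),
    label = label
  )
  regions <- tibble(
    region = c("tmd_n", "cleavage", "anchor"),
    start = c(jmd_len + 1L, jmd_len + 17L, jmd_len + 21L),
    stop = c(jmd_len + 10L, jmd_len + 20L, jmd_len + 24L)
  )
  list(
    data = data,
    truth = list(
      true_class = setNames(true_class, data$id),
      regions = regions,
      pools = SIGNATURE_POOLS,
      effect = effect,
      seed = seed
    )
  )
}

#' Generate a synthetic amino-acid scale set
#'
#' Random min-max normalized scales with subcategory labels, guaranteed to
#' contain one charge-like scale (high for K/R) and one size-like scale
#' (low for G/A/S) so that a planted physicochemical signature is
#' detectable, plus a branched-hydrophobicity scale favouring V/I/T.
#'
#' @param n_scales Number of scales (must be at least `n_subcategories`).
#' @param n_subcategories Number of distinct subcategory labels (default 8).
#' @param seed Random seed.
#' @return A normalized scale tibble (`scale_id`, 20 residue columns,
#'   `category`, `subcategory`).
#' @export
synth_scaleset <- function(n_scales = 25, n_subcategories = 8, seed = 1) {
  if (n_scales < n_subcategories) abort("n_scales must be >= n_subcategories")
  if (n_scales < 3) abort("need at least 3 scales for the anchored trio")
  set.seed(seed)
  vals <- matrix(runif(n_scales * 20), nrow = n_scales,
                 dimnames = list(NULL, AA_ALPHABET))
  # anchored scales: charge-, size-, and branched-hydrophobicity-like
  vals[1, ] <- runif(20, 0, 0.25)
  vals[1, c("K", "R")] <- runif(2, 0.85, 1)
  vals[1, c("D", "E")] <- runif(2, 0, 0.05)
  vals[2, ] <- runif(20, 0.5, 1)
  vals[2, c("G", "A", "S")] <- runif(3, 0, 0.15)
  vals[3, ] <- runif(20, 0, 0.4)
  vals[3, c("V", "I", "T")] <- runif(3, 0.8, 1)
  df <- as_tibble(vals) |>
    mutate(
      scale_id = sprintf("SYNSC%03d", seq_len(n_scales)),
      category = paste0("cat_", (seq_len(n_scales) - 1) %% 3 + 1),
      subcategory = paste0("subcat_", (seq_len(n_scales) - 1) %% n_subcategories + 1),
      .before = 1
    )
  suppressMessages(normalize_scales(df))
}

#' Recovery metrics against the planted ground truth
#'
#' Scores how well a CPP run or a set of prediction scores recovers the
#' planted signature: positional recall/precision of the top features'
#' reference-frame positions against the planted regions, and balanced
#' accuracy of predicted classes against the true classes.
#'
#' @param truth Ground-truth list from [synth_dataset()].
#' @param cpp A `cpp_result` (optional).
#' @param scores Tibble with `id` and `score` in `[0, 1]` (optional).
#' @param top_n Number of top-ranked features to assess (default 10).
#' @return A one-row tibble with `positional_recall`,
#'   `positional_precision` (when `cpp` given) and `balanced_accuracy`
#'   (when `scores` given).
#' @export
truth_report <- function(truth, cpp = NULL, scores = NULL, top_n = 10) {
  out <- tibble(.rows = 1)
  planted <- unlist(purrr::map2(truth$regions$start, truth$regions$stop, seq))
  if (!is.null(cpp)) {
    top <- head(cpp$features, top_n)
    pos <- unlist(top$positions)
    out$positional_recall <- mean(pos %in% planted)
    out$positional_precision <- length(intersect(pos, planted)) /
      length(unique(pos))
  }
  if (!is.null(scores)) {
    unknown <- setdiff(scores$id, names(truth$true_class))
    if (length(unknown) > 0) {
      abort(paste0("ids not in ground truth: ",
                   paste(head(unknown, 3), collapse = ", ")))
    }
    tc <- truth$true_class[scores$id]
    out$balanced_accuracy <- balanced_accuracy(tc == "positive",
                                               scores$score >= 0.5)
  }
  out
}
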