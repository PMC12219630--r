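#' Normalize an amino-acid scale table
#'
#' Takes a table with one row per scale and one numeric column per residue
#' letter, min-max normalizes each scale to [0, 1], and drops scales that
#' cannot be used: rows with missing values, constant rows (zero range), and
#' exact duplicates of an earlier row (after normalization). Counts of
#' dropped scales are reported via a message.
#'
#' @param data Data frame with columns `scale_id`, the 20 residue letters
#'   (see [aa_alphabet()]), and optionally `category` and `subcategory`.
#' @return A tibble of normalized scales; attribute `dropped` records the
#'   per-reason drop counts.
#' @export
normalize_scales <- function(data) {
  data <- as_tibble(data)
  if (!"scale_id" %in% names(data)) abort("missing column: scale_id")
  missing_aa <- setdiff(AA_ALPHABET, names(data))
  if (length(missing_aa) > 0) {
    abort(paste0("missing residue columns: ", paste(missing_aa, collapse = ", ")))
  }
  vals <- as.matrix(data[, AA_ALPHABET])
  if (!is.numeric(vals)) abort("residue columns must be numeric")
  if (anyDuplicated(data$scale_id)) abort("scale ids must be unique")

  has_na <- apply(vals, 1, anyNA)
  rng <- apply(vals, 1, function(v) diff(range(v)))
  constant <- !has_na & rng == 0

  keep <- !has_na & !constant
  vals <- vals[keep, , drop = FALSE]
  out <- data[keep, , drop = FALSE]
  vals <- (vals - apply(vals, 1, min)) / apply(vals, 1, function(v) diff(range(v)))
  out[, AA_ALPHABET] <- vals

  dup <- duplicated(round(vals, 12))
  out <- out[!dup, , drop = FALSE]

  dropped <- c(missing = sum(has_na), constant = sum(constant), duplicate = sum(dup))
  if (sum(dropped) > 0) {
    inform(paste0("dropped scales - missing: ", dropped[["missing"]],
                  ", constant: ", dropped[["constant"]],
                  ", duplicate: ", dropped[["duplicate"]]))
  }
  if (!"category" %in% names(out)) out$category <- NA_character_
  if (!"subcategory" %in% names(out)) out$subcategory <- NA_character_
  attr(out, "dropped") <- dropped
  out
}

#' Read and normalize a scale TSV
#'
#' Reads a tab-separated scale table (columns `scale_id`, one per residue
#' letter, optional `category`/`subcategory`) and applies
#' [normalize_scales()]. A separate classification table can be joined by
#' `scale_id`.
#'
#' @param path Path to the scale TSV.
#' @param classification Optional data frame with `scale_id`, `category`,
#'   `subcategory` to join.
#' @return A normalized scale tibble.
#' @export
read_scales <- function(path, classification = NULL) {
  data <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(classification)) {
    data <- left_join(data,
                      select(as_tibble(classification), "scale_id",
                             dplyr::any_of(c("category", "subcategory"))),
                      by = "scale_id")
  }
  normalize_scales(data)
}

# scale tibble -> 20 x n matrix, rows in AA_ALPHABET order, cols named by id
scale_matrix <- function(scales) {
  m <- t(as.matrix(scales[, AA_ALPHABET]))
  colnames(m) <- scales$scale_id
  m
}

#' Mean scale value over selected residues
#'
#' The elementary CPP feature value: each selected residue is assigned its
#' min-max normalized scale value and the values are averaged. Returns `NA`
#' for an empty selection (a split that is not applicable to the part).
#'
#' @param part_sequence Amino-acid string of the part.
#' @param indices 1-based residue indices selected by a split (may be `NULL`).
#' @param scale One scale: either a named numeric vector over the 20 letters
#'   or a single row of a scale tibble.
#' @return A number in `[0, 1]`, or `NA_real_` when not applicable.
#' @export
feature_value <- function(part_sequence, indices, scale) {
  if (is.null(indices) || length(indices) == 0) return(NA_real_)
  if (is.data.frame(scale)) scale <- unlist(scale[1, AA_ALPHABET])
  codes <- encode_sequence(part_sequence)
  if (any(indices < 1 | indices > length(codes))) abort("indices out of range")
  mean(scale[AA_ALPHABET][codes[indices]])
}

#' Redundancy-reduce a scale set with subcategory coverage
#'
#' Agglomerative clustering (complete linkage by default) of scales on the
#' distance `1 - Pearson correlation` between their 20-residue vectors, with
#' one representative per cluster: the medoid, i.e. the scale with the
#' highest mean correlation to its cluster members (ties broken by
#' lexicographically smallest id). The number of clusters is the smallest
#' `k` -- scanned upward from the number of distinct subcategories -- for
#' which every subcategory of the input appears among the representatives.
#' The result is invariant to input row order.
#'
#' @param scales A normalized scale tibble with `subcategory` populated.
#' @param subcategories Subcategories that must be covered; defaults to all
#'   subcategories present in the input. A requested subcategory with no
#'   scale is an error.
#' @param linkage Linkage method for [stats::hclust()] (default
#'   `"complete"`).
#' @return The selected scales as a tibble (subset of the input rows,
#'   ordered by id), with attribute `k` holding the cluster count used.
#' @export
aaclust_select <- function(scales, subcategories = NULL, linkage = "complete") {
  scales <- arrange(as_tibble(scales), .data$scale_id)
  if (anyNA(scales$subcategory)) abort("all scales need a subcategory")
  subcats <- subcategories %||% unique(scales$subcategory)
  orphan <- setdiff(subcats, scales$subcategory)
  if (length(orphan) > 0) {
    abort(paste0("no scale for subcategory: ", paste(orphan, collapse = ", ")))
  }
  n <- nrow(scales)
  if (n == 0) abort("empty scale set")

  m <- scale_matrix(scales)
  cm <- suppressWarnings(cor(m))
  cm[is.na(cm)] <- 0 # constant scales are rejected upstream; guard anyway
  d <- as.dist(1 - cm)
  hc <- hclust(d, method = linkage)

  medoid <- function(members) {
    if (length(members) == 1) return(members)
    sub <- cm[members, members, drop = FALSE]
    score <- rowMeans(sub)
    members[order(-score, members)][1]
  }
  for (k in seq(length(subcats), n)) {
    cl <- cutree(hc, k = k)
    reps <- vapply(split(names(cl), cl), medoid, character(1))
    covered <- unique(scales$subcategory[match(reps, scales$scale_id)])
    if (all(subcats %in% covered)) {
      out <- filter(scales, .data$scale_id %in% reps) |> arrange(.data$scale_id)
      attr(out, "k") <- k
      return(out)
    }
  }
  # k = n always covers every subcategory, so this is unreachable
  abort("no cluster count covers all subcategories")
}
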