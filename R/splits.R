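#' Enumerate segment splits
#'
#' Segments are continuous subsequences: a part is cut into `n` equally
#' sized pieces and one piece is the split. Enumerating `n` from `n_min` to
#' `n_max` and taking every `i`-th piece yields `sum(n_min..n_max)` splits
#' (120 at the defaults 1..15).
#'
#' @param n_min,n_max Segment-count range (defaults 1 and 15).
#' @return A tibble of split specifications with columns `kind`, `n_split`,
#'   `i_split`, `terminus`, `start`, `steps`, `span` (minimum part length at
#'   which the split selects at least one residue).
#' @export
enumerate_segments <- function(n_min = 1, n_max = 15) {
  if (n_min < 1 || n_min > n_max) abort("need 1 <= n_min <= n_max")
  grid <- tidyr::expand_grid(n_split = n_min:n_max) |>
    mutate(i_split = map(.data$n_split, seq_len)) |>
    tidyr::unnest("i_split")
  tibble(
    kind = "segment",
    n_split = as.integer(grid$n_split),
    i_split = as.integer(grid$i_split),
    terminus = NA_character_,
    start = NA_integer_,
    steps = NA_character_,
    span = as.integer(grid$n_split) # non-empty requires L >= n
  )
}

# all step sequences over `steps` of length 1..(max_res - 1)
step_sequences <- function(steps = c(3, 4), n_res = 2:4) {
  out <- list()
  for (k in sort(n_res) - 1) {
    grids <- rep(list(steps), k)
    combos <- do.call(tidyr::expand_grid, setNames(grids, paste0("s", seq_len(k))))
    # expand_grid varies the last column fastest; enforce lexicographic order
    combos <- combos[do.call(order, as.list(combos)), , drop = FALSE]
    out <- c(out, lapply(seq_len(nrow(combos)), function(i) as.integer(unlist(combos[i, ]))))
  }
  out
}

#' Enumerate pattern splits
#'
#' Patterns are discontinuous subsequences of 2--4 residues separated by 3 or
#' 4 positions (one or two helical turns), anchored at either the N- or the
#' C-terminal end of a part. All step sequences over `steps` with total span
#' (1 + sum of steps) at most `span_max` are combined with every start
#' offset that keeps the pattern inside the first `span_max` positions; this
#' yields 182 patterns at the defaults (91 per terminus).
#'
#' @param steps Allowed gaps between consecutive selected residues.
#' @param n_res Allowed numbers of selected residues.
#' @param span_max Window cap within which a pattern must fit (default 15).
#' @param termini Anchoring termini, subset of `c("N", "C")`.
#' @return A tibble of split specifications (see [enumerate_segments()]);
#'   `steps` holds the dash-separated step sequence, `span` the full extent
#'   `1 + sum(steps) + start - 1` needed for applicability.
#' @export
enumerate_patterns <- function(steps = c(3, 4), n_res = 2:4, span_max = 15,
                               termini = c("N", "C")) {
  seqs <- step_sequences(steps, n_res)
  rows <- list()
  for (term in termini) {
    for (s in seqs) {
      extent <- 1L + sum(s)
      if (extent > span_max) next
      for (start in seq_len(span_max - extent + 1L)) {
        rows[[length(rows) + 1L]] <- tibble(
          kind = "pattern",
          n_split = NA_integer_, i_split = NA_integer_,
          terminus = term,
          start = as.integer(start),
          steps = paste(s, collapse = "-"),
          span = as.integer(start + extent - 1L)
        )
      }
    }
  }
  bind_rows(rows)
}

periodic_variants <- list(
  "3-only"      = c(3L, 3L),
  "4-only"      = c(4L, 4L),
  "alt-3-first" = c(3L, 4L),
  "alt-4-first" = c(4L, 3L)
)

#' Enumerate periodic-pattern splits
#'
#' Periodic patterns select every third, fourth, or alternating third and
#' fourth residue across a whole part, mirroring the i, i+3/i+4 periodicity
#' of an alpha-helix face. Four step variants with start offsets `1..first
#' step`, anchored from both termini, give 28 splits at the defaults.
#'
#' @param termini Anchoring termini, subset of `c("N", "C")`.
#' @return A tibble of split specifications; `steps` holds the variant id.
#' @export
enumerate_periodic <- function(termini = c("N", "C")) {
  rows <- list()
  for (term in termini) {
    for (variant in names(periodic_variants)) {
      first_step <- periodic_variants[[variant]][1]
      for (start in seq_len(first_step)) {
        rows[[length(rows) + 1L]] <- tibble(
          kind = "periodic",
          n_split = NA_integer_, i_split = NA_integer_,
          terminus = term,
          start = as.integer(start),
          steps = variant,
          span = as.integer(start)
        )
      }
    }
  }
  bind_rows(rows)
}

#' Enumerate the full split universe
#'
#' Concatenates segments, patterns, and periodic patterns in a fixed order
#' and assigns stable integer split ids; 330 splits at the defaults
#' (120 + 182 + 28). The enumeration is a pure function of its parameters,
#' so ids are reproducible across runs.
#'
#' @inheritParams enumerate_segments
#' @inheritParams enumerate_patterns
#' @return A tibble with `split_id` prepended to the specification columns.
#' @export
cpp_splits <- function(n_min = 1, n_max = 15, steps = c(3, 4), n_res = 2:4,
                       span_max = 15, termini = c("N", "C")) {
  out <- bind_rows(
    enumerate_segments(n_min, n_max),
    enumerate_patterns(steps, n_res, span_max, termini),
    enumerate_periodic(termini)
  )
  out$split_id <- seq_len(nrow(out))
  select(out, "split_id", dplyr::everything())
}

#' Resolve a split to residue indices
#'
#' Maps one split specification to the 1-based residue indices it selects on
#' a part of length `L`. Segment `i` of `n` covers indices
#' `floor((i-1)*L/n)+1 .. floor(i*L/n)`, so the `n` segments always
#' partition `1..L`. N-anchored patterns start at `start` and advance by
#' their step sequence; C-anchored splits are the mirror image (each
#' N-anchored index `p` maps to `L - p + 1`), returned in ascending order.
#' Periodic patterns advance by their (possibly alternating) steps until the
#' part ends.
#'
#' A split whose span exceeds `L` (or an empty segment when `n > L`) is not
#' applicable: the feature value is undefined there, and `NULL` is returned
#' rather than an empty selection.
#'
#' @param spec One row of a split table (as a data frame or list).
#' @param L Part length.
#' @return Integer vector of selected indices, or `NULL` if not applicable.
#' @export
resolve_split <- function(spec, L) {
  if (L < 1) return(NULL)
  kind <- spec$kind
  if (kind == "segment") {
    lo <- floor((spec$i_split - 1) * L / spec$n_split) + 1L
    hi <- floor(spec$i_split * L / spec$n_split)
    if (hi < lo) return(NULL)
    return(as.integer(lo:hi))
  }
  if (kind == "pattern") {
    if (L < spec$span) return(NULL)
    st <- as.integer(strsplit(spec$steps, "-", fixed = TRUE)[[1]])
    idx <- spec$start + c(0L, cumsum(st))
  } else if (kind == "periodic") {
    if (L < spec$span) return(NULL)
    st <- periodic_variants[[spec$steps]]
    idx <- spec$start
    k <- 0L
    repeat {
      nxt <- idx[length(idx)] + st[k %% 2L + 1L]
      if (nxt > L) break
      idx <- c(idx, nxt)
      k <- k + 1L
    }
  } else {
    abort(paste0("unknown split kind: ", kind))
  }
  if (identical(spec$terminus, "C")) idx <- sort(L - idx + 1L)
  as.integer(idx)
}

#' Resolve every split for a part length
#'
#' Vectorised companion of [resolve_split()]: resolves each row of a split
#' table on a part of length `L`.
#'
#' @param splits A split table from [cpp_splits()].
#' @param L Part length.
#' @return A list (one element per split) of index vectors or `NULL`.
#' @export
resolve_splits <- function(splits, L) {
  lapply(seq_len(nrow(splits)), function(i) resolve_split(splits[i, ], L))
}
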