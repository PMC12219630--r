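#' Validate annotated membrane-protein entries
#'
#' Checks a protein annotation table against the structural requirements of
#' the part coordinate system: transmembrane domain (TMD) boundaries must lie
#' within the sequence, the sequence must use canonical amino-acid letters,
#' and at least `jmd_len` residues must flank the TMD on both sides so that
#' full-length juxtamembrane domains (JMDs) can be extracted. Entries that
#' fail are flagged, never silently padded; the reason code distinguishes
#' malformed annotations (`bad_indices`, `bad_alphabet`, `bad_label`,
#' `duplicate_id`) from biologically valid but too-short flanks
#' (`short_jmd_n`, `short_jmd_c`).
#'
#' @param data A data frame with columns `id`, `sequence`, `tmd_start`,
#'   `tmd_stop` and optionally `label` (one of `"positive"`, `"negative"`,
#'   `"unlabeled"`).
#' @param jmd_len Required juxtamembrane length on each side (default 10).
#' @return The input as a tibble with logical column `valid` and character
#'   column `reason` (`"ok"` for valid rows).
#' @export
validate_entries <- function(data, jmd_len = 10) {
  data <- as_tibble(data)
  required <- c("id", "sequence", "tmd_start", "tmd_stop")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (!"label" %in% names(data)) data$label <- "unlabeled"
  if (jmd_len < 4) abort("jmd_len must be >= 4 (the TMD-C anchor needs 4 residues)")

  seq_len_ <- nchar(data$sequence)
  reason <- rep("ok", nrow(data))

  bad_idx <- is.na(data$tmd_start) | is.na(data$tmd_stop) |
    data$tmd_start < 1 | data$tmd_stop < data$tmd_start |
    data$tmd_stop > seq_len_
  reason[bad_idx] <- "bad_indices"

  bad_alpha <- !grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"),
                      data$sequence)
  reason[reason == "ok" & bad_alpha] <- "bad_alphabet"

  bad_label <- !data$label %in% c("positive", "negative", "unlabeled")
  reason[reason == "ok" & bad_label] <- "bad_label"

  dup <- duplicated(data$id)
  reason[reason == "ok" & dup] <- "duplicate_id"

  short_n <- (data$tmd_start - 1) < jmd_len
  short_c <- (seq_len_ - data$tmd_stop) < jmd_len
  reason[reason == "ok" & short_n] <- "short_jmd_n"
  reason[reason == "ok" & short_c] <- "short_jmd_c"

  data$valid <- reason == "ok"
  data$reason <- reason
  data
}

# offsets (0-based) of each part within the JMD-N|TMD|JMD-C frame
part_offset <- function(part, tmd_len, jmd_len = 10, ext_len = 4) {
  n_half <- ceiling(tmd_len / 2)
  switch(part,
    jmd_n       = 0L,
    tmd         = jmd_len,
    tmd_n       = jmd_len,
    tmd_c       = jmd_len + n_half,
    tmd_e       = jmd_len - ext_len,
    jmd_c       = jmd_len + tmd_len,
    jmd_n_tmd_n = 0L,
    tmd_c_jmd_c = jmd_len + n_half,
    tmd_jmd     = 0L,
    abort(paste0("unknown part: ", part))
  )
}

# length of each part given TMD length
part_length <- function(part, tmd_len, jmd_len = 10, ext_len = 4) {
  n_half <- ceiling(tmd_len / 2)
  switch(part,
    jmd_n       = jmd_len,
    tmd         = tmd_len,
    tmd_n       = n_half,
    tmd_c       = tmd_len - n_half,
    tmd_e       = tmd_len + 2 * ext_len,
    jmd_c       = jmd_len,
    jmd_n_tmd_n = jmd_len + n_half,
    tmd_c_jmd_c = (tmd_len - n_half) + jmd_len,
    tmd_jmd     = jmd_len + tmd_len + jmd_len,
    abort(paste0("unknown part: ", part))
  )
}

#' Part identifiers
#'
#' All sequence parts derivable from a validated entry: the TMD, its N- and
#' C-terminal halves, the TMD extended by `ext_len` residues on both sides
#' (TMD-E), the flanking juxtamembrane domains, and their combinations.
#'
#' @return Character vector of part ids.
#' @export
part_ids <- function() {
  c("jmd_n", "tmd", "tmd_n", "tmd_c", "tmd_e", "jmd_c",
    "jmd_n_tmd_n", "tmd_c_jmd_c", "tmd_jmd")
}

#' Derive sequence parts from validated entries
#'
#' Extracts every sequence part for each valid entry. The TMD of length L is
#' split into an N-terminal half of `ceiling(L/2)` residues and a C-terminal
#' half holding the remainder (the extra residue of an odd-length TMD goes to
#' the N-half; this convention is fixed). The TMD-C anchor is the first four
#' residues of the JMD-C, the region that typically carries the basic
#' residues anchoring the helix at the membrane-water interface.
#'
#' @inheritParams validate_entries
#' @param ext_len Extension of the TMD on each side for the TMD-E part
#'   (default 4).
#' @param drop_invalid Drop entries failing validation (default `TRUE`,
#'   with a message); otherwise invalid entries raise an error.
#' @return A tibble with one row per protein: `id`, `label`, `tmd_len`, one
#'   column per part id, and `anchor`.
#' @export
derive_parts <- function(data, jmd_len = 10, ext_len = 4, drop_invalid = TRUE) {
  if (ext_len < 0) abort("ext_len must be >= 0")
  if (ext_len > jmd_len) abort("ext_len must not exceed jmd_len")
  checked <- validate_entries(data, jmd_len = jmd_len)
  n_bad <- sum(!checked$valid)
  if (n_bad > 0) {
    if (!drop_invalid) {
      abort(paste0(n_bad, " invalid entries; first reason: ",
                   checked$reason[!checked$valid][1]))
    }
    dropped <- dplyr::count(filter(checked, !.data$valid), .data$reason)
    inform(paste0(
      "dropping ", n_bad, " invalid entries (",
      paste(paste0(dropped$reason, ": ", dropped$n), collapse = ", "), ")"
    ))
    checked <- filter(checked, .data$valid)
  }
  if (nrow(checked) == 0) abort("no valid entries")

  sub_part <- function(seq, start, stop) substr(seq, start, stop)
  out <- checked |>
    mutate(
      tmd_len = .data$tmd_stop - .data$tmd_start + 1L,
      n_half  = ceiling(.data$tmd_len / 2),
      jmd_n   = sub_part(.data$sequence, .data$tmd_start - jmd_len, .data$tmd_start - 1L),
      tmd     = sub_part(.data$sequence, .data$tmd_start, .data$tmd_stop),
      tmd_n   = sub_part(.data$sequence, .data$tmd_start, .data$tmd_start + .data$n_half - 1L),
      tmd_c   = sub_part(.data$sequence, .data$tmd_start + .data$n_half, .data$tmd_stop),
      tmd_e   = sub_part(.data$sequence, .data$tmd_start - ext_len, .data$tmd_stop + ext_len),
      jmd_c   = sub_part(.data$sequence, .data$tmd_stop + 1L, .data$tmd_stop + jmd_len),
      jmd_n_tmd_n = paste0(.data$jmd_n, .data$tmd_n),
      tmd_c_jmd_c = paste0(.data$tmd_c, .data$jmd_c),
      tmd_jmd = paste0(.data$jmd_n, .data$tmd, .data$jmd_c),
      anchor  = substr(.data$jmd_c, 1L, 4L)
    ) |>
    select(dplyr::any_of(c("id", "name", "label", "tmd_len")),
           dplyr::all_of(part_ids()), "anchor")
  attr(out, "jmd_len") <- jmd_len
  attr(out, "ext_len") <- ext_len
  out
}

#' Map a part-local residue index to the TMD-JMD frame
#'
#' Converts a 1-based index within a named part into the 1-based position in
#' the concatenated JMD-N|TMD|JMD-C coordinate frame of the same protein.
#' Used to place split-selected residues of any part onto a common positional
#' axis for per-residue profiles and maps.
#'
#' @param part A part id (see [part_ids()]).
#' @param index 1-based residue index (vectorised) within the part.
#' @param tmd_len TMD length of the protein (or reference frame).
#' @param jmd_len,ext_len Part configuration; defaults 10 and 4.
#' @return Integer vector of positions in `1..(2*jmd_len + tmd_len)`.
#' @export
tmd_jmd_position <- function(part, index, tmd_len, jmd_len = 10, ext_len = 4) {
  len <- part_length(part, tmd_len, jmd_len, ext_len)
  if (any(index < 1 | index > len)) {
    abort(paste0("index out of range 1..", len, " for part ", part))
  }
  as.integer(part_offset(part, tmd_len, jmd_len, ext_len) + index)
}
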