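#' Read a protein dataset from FASTA plus annotation TSV
#'
#' Merges a FASTA file of amino-acid sequences with a tab-separated
#' annotation table (`id`, `tmd_start`, `tmd_stop`, optional `label`,
#' header required) into a protein tibble. Alternatively the annotation
#' table may carry a `sequence` column, in which case the FASTA is
#' optional. Every annotation row must have a sequence; duplicate ids are
#' an error.
#'
#' @param annot_path Path to the annotation TSV.
#' @param fasta_path Optional path to a FASTA file with ids matching the
#'   annotation.
#' @return A validated protein tibble (invalid rows flagged, not dropped);
#'   see [validate_entries()].
#' @export
read_dataset <- function(annot_path, fasta_path = NULL) {
  annot <- readr::read_tsv(annot_path, show_col_types = FALSE,
                           progress = FALSE)
  if (!"id" %in% names(annot)) abort("annotation needs an 'id' column")
  if (anyDuplicated(annot$id)) {
    abort(paste0("duplicate annotation id: ",
                 annot$id[duplicated(annot$id)][1]))
  }
  if (!is.null(fasta_path)) {
    seqs <- Biostrings::readAAStringSet(fasta_path)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    if (anyDuplicated(names(seqs))) abort("duplicate FASTA id")
    missing <- setdiff(annot$id, names(seqs))
    if (length(missing) > 0) {
      abort(paste0("annotation id without FASTA record: ", missing[1]))
    }
    annot$sequence <- unname(as.character(seqs[annot$id]))
  }
  if (!"sequence" %in% names(annot)) {
    abort("no sequences: provide fasta_path or a 'sequence' column")
  }
  validate_entries(annot)
}

#' Write a protein dataset to FASTA plus annotation TSV
#'
#' Round-trip companion of [read_dataset()].
#'
#' @param data Protein tibble (`id`, `sequence`, `tmd_start`, `tmd_stop`,
#'   `label`).
#' @param annot_path,fasta_path Output paths.
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(data, annot_path, fasta_path = NULL) {
  if (!is.null(fasta_path)) {
    seqs <- Biostrings::AAStringSet(setNames(data$sequence, data$id))
    Biostrings::writeXStringSet(seqs, fasta_path)
    data <- select(data, -"sequence")
  }
  readr::write_tsv(
    select(data, dplyr::any_of(c("id", "sequence", "tmd_start", "tmd_stop",
                                 "label"))),
    annot_path
  )
  invisible(c(annot = annot_path, fasta = fasta_path))
}

#' Write result tables and figures with a manifest
#'
#' Writes each table as a TSV and each figure as a PNG into `out_dir`, then
#' writes `manifest.json` listing every product together with a hash of the
#' configuration, so a run can be audited and reproduced.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if missing).
#' @param figures Named list of ggplot objects (optional).
#' @param config List of the effective configuration to hash (optional).
#' @return The manifest as a list, invisibly; also written as JSON.
#' @export
write_outputs <- function(tables, out_dir, figures = list(), config = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(tables)) {
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    tab <- tables[[nm]]
    tab <- mutate(as_tibble(tab),
                  across(dplyr::where(is.list),
                         ~ map_chr(.x, paste, collapse = ",")))
    readr::write_tsv(tab, path)
    files <- c(files, basename(path))
  }
  for (nm in names(figures)) {
    path <- file.path(out_dir, paste0(nm, ".png"))
    ggplot2::ggsave(path, figures[[nm]], width = 8, height = 4.5, dpi = 150)
    files <- c(files, basename(path))
  }
  manifest <- list(
    files = files,
    config = config,
    config_hash = rlang::hash(config),
    written = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

cli_usage <- function() {
  paste(
    "usage: cpprofiler <subcommand> [options]",
    "",
    "subcommands:",
    "  simulate   generate a synthetic dataset (FASTA + TSV + truth JSON)",
    "  parts      derive sequence parts from a dataset",
    "  splits     dump the split universe as TSV",
    "  cpp        run the CPP feature-engineering pipeline",
    "  dpulearn   identify reliable negatives from unlabeled data",
    "  train      Monte Carlo ensemble training",
    "  predict    score proteins with a trained ensemble",
    "  explain    tree-SHAP explanation of one protein",
    "",
    "run 'cpprofiler <subcommand> --help' for options",
    sep = "\n"
  )
}

cli_opt <- function(args, flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 0) return(default)
  if (i[1] == length(args)) abort(paste0(flag, " needs a value"))
  args[i[1] + 1]
}

#' Command-line entry point
#'
#' Thin dispatcher over the package's functions, used by the
#' `inst/cli/cpprofiler.R` script. Flags mirror the function arguments;
#' every run logs the effective parameter values.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
cpp_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0 || args[1] %in% c("--help", "-h", "help")) {
    cat(cli_usage(), "\n")
    return(invisible(0L))
  }
  sub <- args[1]
  rest <- args[-1]
  known <- c("simulate", "parts", "splits", "cpp", "dpulearn", "train",
             "predict", "explain")
  if (!sub %in% known) {
    message("unknown subcommand: ", sub, "\n", cli_usage())
    return(invisible(1L))
  }
  out <- cli_opt(rest, "--out", "cpprofiler_out")
  status <- tryCatch({
    switch(sub,
      simulate = {
        sim <- synth_dataset(
          n_pos = as.integer(cli_opt(rest, "--n-pos", 63)),
          n_neg = as.integer(cli_opt(rest, "--n-neg", 14)),
          n_unlabeled = as.integer(cli_opt(rest, "--n-unlabeled", 631)),
          effect = as.numeric(cli_opt(rest, "--effect", 1)),
          seed = as.integer(cli_opt(rest, "--seed", 1))
        )
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        write_dataset(sim$data, file.path(out, "annotation.tsv"),
                      file.path(out, "sequences.fasta"))
        jsonlite::write_json(
          list(true_class = as.list(sim$truth$true_class),
               regions = sim$truth$regions, effect = sim$truth$effect),
          file.path(out, "truth.json"), auto_unbox = TRUE
        )
        inform(paste0("wrote ", nrow(sim$data), " proteins to ", out))
      },
      parts = {
        data <- read_dataset(cli_opt(rest, "--annot"),
                             cli_opt(rest, "--fasta"))
        parts <- derive_parts(data,
                              jmd_len = as.integer(cli_opt(rest, "--jmd-len", 10)),
                              ext_len = as.integer(cli_opt(rest, "--ext-len", 4)))
        readr::write_tsv(parts, out)
      },
      splits = {
        readr::write_tsv(cpp_splits(), out)
      },
      cpp = {
        data <- read_dataset(cli_opt(rest, "--annot"),
                             cli_opt(rest, "--fasta"))
        scales <- read_scales(cli_opt(rest, "--scales"))
        res <- cpp_run(
          data, scales,
          n_filter = as.integer(cli_opt(rest, "--n-filter", 100)),
          max_std_test = as.numeric(cli_opt(rest, "--max-std-test", 0.2)),
          pct_pre_filter = as.numeric(cli_opt(rest, "--pct-pre-filter", 0.05)),
          max_overlap = as.numeric(cli_opt(rest, "--max-overlap", 0.5)),
          max_cor = as.numeric(cli_opt(rest, "--max-cor", 0.5))
        )
        agg <- positional_aggregation(res$features)
        write_outputs(
          tables = list(features = tidy(res), profile = agg$profile,
                        feature_map = agg$feature_map),
          figures = list(profile = ggplot2::autoplot(res)),
          out_dir = out, config = res$config
        )
      },
      dpulearn = {
        data <- read_dataset(cli_opt(rest, "--annot"),
                             cli_opt(rest, "--fasta"))
        scales <- read_scales(cli_opt(rest, "--scales"))
        res <- cpp_run(data, scales)
        n_needed <- cli_opt(rest, "--n-needed", "auto")
        if (n_needed != "auto") n_needed <- as.integer(n_needed)
        pu <- dpulearn(res$matrix, res$labels, n_needed = n_needed)
        readr::write_tsv(tidy(pu), out)
      },
      train = ,
      predict = ,
      explain = {
        message("subcommand '", sub, "' is exposed as R functions ",
                "(monte_carlo_train, predict_score, mean_shap/fuzzy_shap); ",
                "see the package manual")
        return(invisible(1L))
      }
    )
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
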