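# Run manifests and machine-readable report assembly.

#' Build a run manifest
#'
#' Records the tool version, seed, configuration digest and the MD5 digest
#' and row/record count of every input and output file, so identical inputs
#' reproduce identical manifests (timestamps are kept in a separate field and
#' excluded from the digest).
#'
#' @param files Named character vector of file paths to digest.
#' @param seed Integer seed used for the run (or `NA`).
#' @param config Optional configuration object; digested via serialization.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(files = character(), seed = NA_integer_,
                         config = NULL) {
  files <- files[file.exists(files)]
  digests <- if (length(files)) tools::md5sum(files) else character(0)
  structure(list(
    tool = "orphanscan",
    version = as.character(utils::packageVersion("orphanscan")),
    seed = seed,
    config_digest = if (is.null(config)) NA_character_ else
      digest_object(config),
    files = data.frame(name = names(files), path = unname(files),
                       md5 = unname(digests), stringsAsFactors = FALSE),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_manifest")
}

digest_object <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf, version = 2, compress = FALSE)
  unname(tools::md5sum(tf))
}

#' Write a run manifest as JSON
#' @param manifest A [run_manifest].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Assemble a machine-readable summary of a pipeline run directory
#'
#' Collects whichever stage outputs exist in `dir` (classification and tally
#' tables, feature class summary, intron bins, chromosome distribution,
#' specificity calls, relative qPCR expression) into one JSON-serializable
#' list; missing outputs are reported under `gaps` rather than failing.
#'
#' @param dir Run directory containing stage output TSVs (the file names
#'   written by the pipeline functions/CLI: `classification.tsv`,
#'   `tally.tsv`, `class_summary.tsv`, `intron_bins.tsv`, `chrom_dist.tsv`,
#'   `calls_*.tsv`, `relative_expression.tsv`).
#' @param path Optional path; when given the report is written as JSON.
#' @return The report list, invisibly when written.
#' @export
assemble_report <- function(dir, path = NULL) {
  read_tsv_if <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) read.delim(p, stringsAsFactors = FALSE) else NULL
  }
  report <- list()
  gaps <- character(0)

  tally <- read_tsv_if("tally.tsv")
  if (!is.null(tally)) {
    fin <- tally[tally$stage == "final_total", , drop = FALSE]
    report$class_totals <- list(
      CONSERVED = fin$n_assigned_conserved[1],
      LINEAGE_SPECIFIC = fin$n_assigned_lineage[1],
      SPECIES_SPECIFIC = fin$n_remaining[1])
    report$stage_tallies <- tally
  } else gaps <- c(gaps, "tally.tsv")

  cls <- read_tsv_if("classification.tsv")
  if (!is.null(cls)) report$n_genes <- nrow(cls) else
    gaps <- c(gaps, "classification.tsv")

  stage_files <- c(class_summary = "class_summary.tsv",
                   intron_bins = "intron_bins.tsv",
                   chrom_distribution = "chrom_dist.tsv",
                   relative_expression = "relative_expression.tsv")
  for (nm in names(stage_files)) {
    d <- read_tsv_if(stage_files[[nm]])
    if (!is.null(d)) report[[nm]] <- d else gaps <- c(gaps, stage_files[[nm]])
  }

  calls <- list.files(dir, pattern = "^calls_.*\\.tsv$")
  if (length(calls)) {
    report$specificity <- lapply(setNames(calls, sub("^calls_|\\.tsv$", "",
                                                     calls)), function(f) {
      d <- read.delim(file.path(dir, f), stringsAsFactors = FALSE)
      list(n_expressed = sum(d$status != "not_expressed"),
           n_unique = sum(d$status == "unique"))
    })
  } else gaps <- c(gaps, "calls_*.tsv")

  report$gaps <- gaps
  if (!is.null(path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "rows")
    return(invisible(report))
  }
  report
}
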