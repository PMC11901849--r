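#' Declare an evidence source
#'
#' An evidence source is one homology comparison in the cascade: a database
#' (or hit table derived from it) together with its taxonomic scope relative
#' to the focal species and the cascade phase it belongs to.
#'
#' @param name Source name, unique within a configuration.
#' @param scope Taxonomic scope of the subjects: `"non_lineage"` (outside the
#'   focal lineage, e.g. non-Apiaceae genomes for coriander),
#'   `"lineage_non_focal"` (inside the lineage but outside the focal genus,
#'   e.g. carrot or celery), or `"focal"` (the focal species itself; such hits
#'   carry no classification information).
#' @param phase `"candidate"` or `"refinement"`.
#' @param search_mode `"prot_vs_prot"` (BLASTP-like), `"prot_vs_nucl"`
#'   (TBLASTN-like) or `"nucl_vs_nucl"` (BLASTN-like).
#' @return A list of class `evidence_source`.
#' @export
evidence_source <- function(name,
                            scope = c("non_lineage", "lineage_non_focal", "focal"),
                            phase = c("candidate", "refinement"),
                            search_mode = c("prot_vs_prot", "prot_vs_nucl",
                                            "nucl_vs_nucl")) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(name = name,
                 scope = match.arg(scope),
                 phase = match.arg(phase),
                 search_mode = match.arg(search_mode)),
            class = "evidence_source")
}

#' Homology hit tables
#'
#' A `hit_table` is a data frame of significant-homology evidence with one row
#' per hit and columns `query_id`, `subject_id`, `source`, `pident`, `length`,
#' `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`, `send`, `evalue`,
#' `bitscore`, plus a `sources` attribute registering every evidence-source
#' name present (so an empty table still knows which source it came from).
#'
#' @param hits A data frame with at least `query_id`, `subject_id`, `source`,
#'   `evalue`, `bitscore`; missing alignment columns are filled with `NA`.
#' @param sources Character vector of source names; defaults to those present
#'   in `hits`.
#' @return A data frame of class `hit_table`.
#' @export
hit_table <- function(hits = NULL, sources = NULL) {
  cols <- c("query_id", "subject_id", "source", "pident", "length",
            "mismatch", "gapopen", "qstart", "qend", "sstart", "send",
            "evalue", "bitscore")
  if (is.null(hits) || nrow(hits) == 0L) {
    hits <- data.frame(query_id = character(), subject_id = character(),
                       source = character(), pident = numeric(),
                       length = integer(), mismatch = integer(),
                       gapopen = integer(), qstart = integer(),
                       qend = integer(), sstart = integer(), send = integer(),
                       evalue = numeric(), bitscore = numeric(),
                       stringsAsFactors = FALSE)
  } else {
    for (col in setdiff(cols, names(hits))) hits[[col]] <- NA
    hits <- as.data.frame(hits)[, cols]
  }
  if (nrow(hits)) {
    if (any(hits$evalue < 0)) stop("E-values must be non-negative")
    pid <- hits$pident[!is.na(hits$pident)]
    if (any(pid < 0 | pid > 100)) stop("percent identity must lie in [0, 100]")
  }
  if (is.null(sources)) sources <- unique(hits$source)
  if (!all(hits$source %in% sources)) {
    stop("hit table contains hits from unregistered source(s): ",
         paste(setdiff(unique(hits$source), sources), collapse = ", "))
  }
  structure(hits, sources = unique(sources),
            class = c("hit_table", "data.frame"))
}

#' Source names registered in a hit table
#' @param table A [hit_table].
#' @return Character vector of source names.
#' @export
hit_sources <- function(table) attr(table, "sources", exact = TRUE)

#' Read a 12-column BLAST tabular (outfmt 6) hit file
#'
#' Expects the standard tab-separated dialect
#' `qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`.  Lines starting with `#` are ignored.  Rows with the
#' wrong column count or a non-numeric E-value raise an error naming the
#' offending line number.
#'
#' @param path Path to the tabular file.
#' @param source An [evidence_source]; every hit is tagged with its name.
#' @return A [hit_table] with `source$name` registered even when empty.
#' @export
read_blast_tabular <- function(path, source) {
  stopifnot(inherits(source, "evidence_source"))
  if (!file.exists(path)) stop("hit table file not found: ", path)
  lines <- readLines(path)
  keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  if (!length(keep)) return(hit_table(sources = source$name))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    bad <- keep[which(nf != 12L)[1L]]
    stop("line ", bad, " of ", path, " has ", nf[which(nf != 12L)[1L]],
         " columns; expected 12")
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  evalue <- suppressWarnings(as.numeric(m[, 11L]))
  if (anyNA(evalue)) {
    bad <- keep[which(is.na(evalue))[1L]]
    stop("line ", bad, " of ", path, " has a non-numeric E-value: '",
         m[which(is.na(evalue))[1L], 11L], "'")
  }
  hits <- data.frame(
    query_id = m[, 1L], subject_id = m[, 2L], source = source$name,
    pident = as.numeric(m[, 3L]), length = as.integer(m[, 4L]),
    mismatch = as.integer(m[, 5L]), gapopen = as.integer(m[, 6L]),
    qstart = as.integer(m[, 7L]), qend = as.integer(m[, 8L]),
    sstart = as.integer(m[, 9L]), send = as.integer(m[, 10L]),
    evalue = evalue, bitscore = as.numeric(m[, 12L]),
    stringsAsFactors = FALSE)
  hit_table(hits, sources = source$name)
}

#' Write a hit table in BLAST tabular (outfmt 6) format
#'
#' @param table A [hit_table].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_blast_tabular <- function(table, path) {
  out <- as.data.frame(table)
  out$source <- NULL
  # match blastn/blastp formatting closely enough to round-trip numerically
  out$evalue <- format(out$evalue, scientific = TRUE, digits = 15)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Keep only significant hits
#'
#' Retains hits whose E-value is strictly below the threshold (the cascade's
#' significance rule is `E < 1e-3`, not `<=`).  Registered sources are
#' preserved, so a source that loses all its hits still counts as screened.
#'
#' @param table A [hit_table].
#' @param threshold Positive E-value cut-off; default `1e-3`.
#' @return A filtered [hit_table].
#' @export
filter_significant <- function(table, threshold = 1e-3) {
  stopifnot(inherits(table, "hit_table"), threshold > 0)
  keep <- table$evalue < threshold
  hit_table(as.data.frame(table)[keep, , drop = FALSE],
            sources = hit_sources(table))
}

#' Optional coverage/identity filter
#'
#' Some screens (e.g. confirming expression evidence from ESTs/PUTs) add a
#' minimum query-coverage and percent-identity requirement on top of the
#' E-value rule.  Hits lacking the alignment columns needed to evaluate a
#' criterion are dropped.
#'
#' @param table A [hit_table].
#' @param min_coverage Minimum query coverage percent (alignment length /
#'   query length * 100); requires `query_lengths`.
#' @param min_identity Minimum percent identity.
#' @param query_lengths Named numeric vector of query sequence lengths,
#'   required when `min_coverage` is used.
#' @return A filtered [hit_table].
#' @export
filter_coverage <- function(table, min_coverage = 70, min_identity = 70,
                            query_lengths = NULL) {
  stopifnot(inherits(table, "hit_table"))
  df <- as.data.frame(table)
  keep <- rep(TRUE, nrow(df))
  if (!is.null(min_identity)) keep <- keep & !is.na(df$pident) & df$pident >= min_identity
  if (!is.null(min_coverage)) {
    if (is.null(query_lengths)) stop("'query_lengths' needed for coverage filtering")
    qlen <- query_lengths[df$query_id]
    cov <- 100 * df$length / qlen
    keep <- keep & !is.na(cov) & cov >= min_coverage
  }
  hit_table(df[keep, , drop = FALSE], sources = hit_sources(table))
}
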