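#' Sequence record collections
#'
#' A `seq_records` object is a plain data frame with columns `id`, `seq` and
#' `kind` (one of `"protein"` or `"nucleotide"`), one row per sequence.  It is
#' the lightweight container passed between the FASTA reader, the built-in
#' similarity search and the simulators.
#'
#' @param id Character vector of unique, non-empty identifiers.
#' @param seq Character vector of non-empty residue strings.
#' @param kind `"protein"` or `"nucleotide"` (recycled to all records).
#' @return A data frame of class `seq_records`.
#' @export
seq_records <- function(id = character(), seq = character(),
                        kind = c("protein", "nucleotide")) {
  kind <- match.arg(kind)
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq)) {
    stop("'id' and 'seq' must have the same length")
  }
  if (any(!nzchar(id))) stop("sequence ids must be non-empty")
  if (anyDuplicated(id)) {
    stop("duplicate sequence id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (any(!nzchar(seq))) {
    stop("empty sequence(s) for id(s): ", paste(id[!nzchar(seq)], collapse = ", "))
  }
  bad <- !grepl(alphabet_regex(kind), seq)
  if (any(bad)) {
    stop("sequence alphabet inconsistent with kind '", kind, "' for id(s): ",
         paste(id[bad], collapse = ", "))
  }
  structure(data.frame(id = id, seq = seq,
                       kind = rep_len(kind, length(id)),
                       stringsAsFactors = FALSE),
            class = c("seq_records", "data.frame"))
}

# IUPAC ambiguity codes are allowed in both alphabets.
alphabet_regex <- function(kind) {
  if (kind == "nucleotide") "^[ACGTUNRYSWKMBDHV]+$" else "^[A-Z*]+$"
}

#' Read a FASTA file into sequence records
#'
#' Headers are split at the first whitespace: the leading token is the record
#' id, the remainder (description) is discarded.  Sequence lines are
#' concatenated and uppercased.  Duplicate ids and empty sequences are errors.
#'
#' @param path Path to a FASTA file.
#' @param kind `"auto"` (default; guessed from residue composition),
#'   `"protein"` or `"nucleotide"`.
#' @return A [seq_records] data frame, in file order.
#' @export
read_fasta <- function(path, kind = c("auto", "protein", "nucleotide")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0L) {
    return(seq_records(kind = if (kind == "auto") "protein" else kind))
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  names(seqs) <- NULL
  if (any(!nzchar(seqs))) {
    stop("empty sequence in ", path, " for id(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  if (anyDuplicated(ids)) {
    stop("duplicate id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (kind == "auto") kind <- guess_alphabet(seqs)
  seq_records(ids, seqs, kind)
}

# A sequence set is called nucleotide when >= 95% of its residues are
# ACGTUN -- ambiguity-free protein sequences rarely reach that.
guess_alphabet <- function(seqs) {
  s <- paste(seqs, collapse = "")
  nt <- sum(strsplit(s, "")[[1]] %in% c("A", "C", "G", "T", "U", "N"))
  if (nt / nchar(s) >= 0.95) "nucleotide" else "protein"
}

#' Write sequence records to a FASTA file
#'
#' @param records A [seq_records] data frame.
#' @param path Output file path.
#' @param width Line width for wrapped sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  set <- Biostrings::BStringSet(setNames(records$seq, records$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
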