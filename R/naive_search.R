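# Built-in deterministic seed-and-extend similarity search.
#
# This is a small test-scale search engine, not a BLAST replica: exact k-mer
# seeds (k = 4 for protein, k = 11 for nucleotide), ungapped extension in both
# directions to the best-scoring containing segment, and a pseudo E-value
# E = K * m * n * exp(-lambda * S) with the fixed constants below (m = query
# length, n = total database length, S = best raw segment score per
# query-subject pair).  Constants follow the published ungapped values for
# the respective scoring schemes.

NAIVE_PROT_K <- 4L
NAIVE_NUCL_K <- 11L
NAIVE_PROT_LAMBDA <- 0.3176
NAIVE_PROT_KCONST <- 0.134
NAIVE_NUCL_MATCH <- 1
NAIVE_NUCL_MISMATCH <- -2
NAIVE_NUCL_LAMBDA <- 1.28
NAIVE_NUCL_KCONST <- 0.46

#' Deterministic seed-and-extend similarity search
#'
#' A self-contained similarity search used to generate homology evidence at
#' test scale (up to a few thousand sequences) without an external aligner.
#' Seeds are exact k-mer matches (k = 4 protein, k = 11 nucleotide; k-mers
#' containing ambiguity codes or stops never seed); each seed is extended
#' without gaps in both directions to the maximum-scoring segment containing
#' it (protein scores from BLOSUM62, nucleotide match +1 / mismatch -2); per
#' query-subject pair the best segment score S over all seeds is converted to
#' a pseudo E-value `E = K * m * n * exp(-lambda * S)`.  In `prot_vs_nucl`
#' mode subjects are translated in all six frames and subject coordinates
#' refer to the translated frame.
#'
#' @param queries,subjects [seq_records] collections.
#' @param mode `"prot_vs_prot"`, `"prot_vs_nucl"` or `"nucl_vs_nucl"`.
#' @param source An [evidence_source] used to tag the hits; its `search_mode`
#'   must agree with `mode`.  Defaults to a candidate-phase source named
#'   `"naive_search"`.
#' @param max_evalue Report hits with pseudo E-value at or below this cap.
#' @return A [hit_table] sorted by `(query_id, evalue)`.
#' @export
naive_search <- function(queries, subjects,
                         mode = c("prot_vs_prot", "prot_vs_nucl", "nucl_vs_nucl"),
                         source = NULL, max_evalue = 10) {
  mode <- match.arg(mode)
  stopifnot(inherits(queries, "seq_records"), inherits(subjects, "seq_records"))
  if (is.null(source)) {
    source <- evidence_source("naive_search", scope = "non_lineage",
                              phase = "candidate", search_mode = mode)
  }
  q_kind <- if (mode == "nucl_vs_nucl") "nucleotide" else "protein"
  s_kind <- if (mode == "prot_vs_prot") "protein" else "nucleotide"
  if (any(queries$kind != q_kind)) {
    stop("mode '", mode, "' expects ", q_kind, " queries")
  }
  if (any(subjects$kind != s_kind)) {
    stop("mode '", mode, "' expects ", s_kind, " subjects")
  }
  db_len <- sum(nchar(subjects$seq))
  if (mode == "prot_vs_nucl") {
    subjects <- translate_six_frames(subjects)
    space <- "protein"
  } else {
    space <- q_kind
  }
  hits <- search_core(queries, subjects, space, db_len, max_evalue)
  if (nrow(hits) && mode == "prot_vs_nucl") {
    # collapse the six frames of one nucleotide subject to its best frame
    frame <- sub("^.*\\|frame=", "", hits$subject_id)
    hits$subject_id <- sub("\\|frame=.*$", "", hits$subject_id)
    hits <- do.call(rbind, lapply(split(hits, hits[c("query_id", "subject_id")],
                                        drop = TRUE), function(d) {
      d[order(d$evalue, -d$bitscore)[1L], , drop = FALSE]
    }))
  }
  if (nrow(hits)) {
    hits$source <- source$name
    hits <- hits[order(hits$query_id, hits$evalue, hits$subject_id), ,
                 drop = FALSE]
    rownames(hits) <- NULL
  }
  hit_table(hits, sources = source$name)
}

translate_six_frames <- function(records) {
  out_id <- character(0); out_seq <- character(0)
  for (i in seq_len(nrow(records))) {
    dna <- Biostrings::DNAString(chartr("U", "T", records$seq[i]))
    rc <- Biostrings::reverseComplement(dna)
    for (f in 1:3) {
      for (strand in c("+", "-")) {
        s <- if (strand == "+") dna else rc
        len <- length(s) - f + 1L
        len <- len - len %% 3L
        if (len < 3L) next
        aa <- suppressWarnings(as.character(Biostrings::translate(
          Biostrings::subseq(s, f, f + len - 1L), if.fuzzy.codon = "X")))
        out_id <- c(out_id, paste0(records$id[i], "|frame=", strand, f))
        out_seq <- c(out_seq, aa)
      }
    }
  }
  seq_records(out_id, out_seq, "protein")
}

# per-residue score lookup and seedable-kmer rule for each search space
search_space <- function(space) {
  if (space == "protein") {
    utils::data("BLOSUM62", package = "Biostrings", envir = environment())
    sm <- get("BLOSUM62", envir = environment())
    list(k = NAIVE_PROT_K, lambda = NAIVE_PROT_LAMBDA, K = NAIVE_PROT_KCONST,
         alphabet = rownames(sm), matrix = sm,
         seed_ok = function(kmer) !grepl("[X*BJZ]", kmer))
  } else {
    alph <- c("A", "C", "G", "T")
    sm <- matrix(NAIVE_NUCL_MISMATCH, 4, 4, dimnames = list(alph, alph))
    diag(sm) <- NAIVE_NUCL_MATCH
    list(k = NAIVE_NUCL_K, lambda = NAIVE_NUCL_LAMBDA, K = NAIVE_NUCL_KCONST,
         alphabet = alph, matrix = sm,
         seed_ok = function(kmer) grepl("^[ACGT]+$", kmer))
  }
}

kmer_table <- function(records, k, seed_ok) {
  out <- lapply(seq_len(nrow(records)), function(i) {
    L <- nchar(records$seq[i])
    if (L < k) return(NULL)
    pos <- seq_len(L - k + 1L)
    data.table::data.table(kmer = substring(records$seq[i], pos, pos + k - 1L),
                           sid = records$id[i], pos = pos)
  })
  dt <- data.table::rbindlist(out)
  if (nrow(dt)) dt <- dt[seed_ok(dt$kmer)]
  dt
}

# scores of residue pairs along one diagonal; NA codes score as the matrix
# minimum (ambiguity codes never help)
diag_scores <- function(qcode, scode, sm) {
  v <- sm[cbind(qcode, scode)]
  v[is.na(v)] <- min(sm)
  v
}

search_core <- function(queries, subjects, space, db_len, max_evalue) {
  sp <- search_space(space)
  k <- sp$k
  qk <- kmer_table(queries, k, sp$seed_ok)
  sk <- kmer_table(subjects, k, sp$seed_ok)
  empty <- data.frame(query_id = character(), subject_id = character(),
                      source = character(), pident = numeric(),
                      length = integer(), mismatch = integer(),
                      gapopen = integer(), qstart = integer(),
                      qend = integer(), sstart = integer(), send = integer(),
                      evalue = numeric(), bitscore = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(qk) || !nrow(sk)) return(empty)
  data.table::setnames(qk, c("sid", "pos"), c("qid", "qpos"))
  seeds <- merge(qk, sk, by = "kmer", allow.cartesian = TRUE)
  if (!nrow(seeds)) return(empty)
  seeds[, `:=`(diag = qpos - pos, kmer = NULL)]
  seeds <- unique(seeds)

  qcodes <- lapply(strsplit(queries$seq, ""), match, sp$alphabet)
  names(qcodes) <- queries$id
  scodes <- lapply(strsplit(subjects$seq, ""), match, sp$alphabet)
  names(scodes) <- subjects$id
  qlen <- setNames(nchar(queries$seq), queries$id)

  rows <- list()
  groups <- split(seeds, seeds[, c("qid", "sid")], drop = TRUE)
  for (g in groups) {
    qid <- g$qid[1L]; sid <- g$sid[1L]
    qc <- qcodes[[qid]]; sc <- scodes[[sid]]
    best <- NULL
    for (d in unique(g$diag)) {
      s0 <- max(1L, 1L - d)
      s1 <- min(length(sc), length(qc) - d)
      L <- s1 - s0 + 1L
      v <- diag_scores(qc[(s0:s1) + d], sc[s0:s1], sp$matrix)
      P <- c(0, cumsum(v))                      # P[i+1] = sum(v[1..i])
      cmin <- cummin(P)
      cmaxr <- rev(cummax(rev(P)))
      a <- g$pos[g$diag == d] - s0 + 1L         # local seed starts
      b <- a + k - 1L
      lg <- ifelse(a > 1L, pmax(0, P[a] - cmin[pmax(a - 1L, 1L)]), 0)
      rg <- ifelse(b < L, pmax(0, cmaxr[pmin(b + 2L, L + 1L)] - P[b + 1L]), 0)
      sc_seed <- P[b + 1L] - P[a] + lg + rg
      i <- which.max(sc_seed)
      if (is.null(best) || sc_seed[i] > best$score) {
        ai <- a[i]; bi <- b[i]
        from <- if (lg[i] > 0) which.min(P[1:(ai - 1L)]) else ai
        to <- if (rg[i] > 0) (bi + 1L) + which.max(P[(bi + 2L):(L + 1L)]) - 1L else bi
        loc <- from:to
        matches <- sum(qc[(s0 + loc - 1L) + d] == sc[s0 + loc - 1L], na.rm = TRUE)
        best <- list(score = sc_seed[i],
                     qstart = s0 + from - 1L + d, qend = s0 + to - 1L + d,
                     sstart = s0 + from - 1L, send = s0 + to - 1L,
                     aln_len = length(loc), matches = matches)
      }
    }
    ev <- sp$K * qlen[[qid]] * db_len * exp(-sp$lambda * best$score)
    if (ev <= max_evalue) {
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = qid, subject_id = sid, source = NA_character_,
        pident = 100 * best$matches / best$aln_len, length = best$aln_len,
        mismatch = best$aln_len - best$matches, gapopen = 0L,
        qstart = best$qstart, qend = best$qend,
        sstart = best$sstart, send = best$send,
        evalue = unname(ev),
        bitscore = (sp$lambda * best$score - log(sp$K)) / log(2),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}
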