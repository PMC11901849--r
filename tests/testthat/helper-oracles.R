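# Independent oracles used by the property tests.  These deliberately share
# no code with the package: plain double loops and explicit while-loop
# extensions.

# Best ungapped segment score per query-subject pair, over all exact k-mer
# seed positions found by brute-force scanning.
oracle_search_scores <- function(queries, subjects, space = c("protein", "nucleotide")) {
  space <- match.arg(space)
  if (space == "protein") {
    data("BLOSUM62", package = "Biostrings", envir = environment())
    sm <- get("BLOSUM62", envir = environment())
    k <- 4L
  } else {
    alph <- c("A", "C", "G", "T")
    sm <- matrix(-2, 4, 4, dimnames = list(alph, alph))
    diag(sm) <- 1
    k <- 11L
  }
  out <- list()
  for (qi in seq_len(nrow(queries))) {
    qc <- strsplit(queries$seq[qi], "")[[1]]
    for (si in seq_len(nrow(subjects))) {
      sc <- strsplit(subjects$seq[si], "")[[1]]
      best <- -Inf
      if (length(qc) >= k && length(sc) >= k) {
        for (i in seq_len(length(qc) - k + 1L)) {
          for (j in seq_len(length(sc) - k + 1L)) {
            if (!all(qc[i:(i + k - 1L)] == sc[j:(j + k - 1L)])) next
            seed <- sum(sm[cbind(qc[i:(i + k - 1L)], sc[j:(j + k - 1L)])])
            gain_l <- 0; cum <- 0; ii <- i - 1L; jj <- j - 1L
            while (ii >= 1L && jj >= 1L) {
              cum <- cum + sm[qc[ii], sc[jj]]
              if (cum > gain_l) gain_l <- cum
              ii <- ii - 1L; jj <- jj - 1L
            }
            gain_r <- 0; cum <- 0; ii <- i + k; jj <- j + k
            while (ii <= length(qc) && jj <= length(sc)) {
              cum <- cum + sm[qc[ii], sc[jj]]
              if (cum > gain_r) gain_r <- cum
              ii <- ii + 1L; jj <- jj + 1L
            }
            sc_total <- seed + gain_l + gain_r
            if (sc_total > best) best <- sc_total
          }
        }
      }
      if (is.finite(best)) {
        out[[length(out) + 1L]] <- data.frame(
          query_id = queries$id[qi], subject_id = subjects$id[si],
          score = best, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(query_id = character(), subject_id = character(),
               score = numeric())
}

# Brute-force scope rule: CONSERVED iff any non-lineage-scoped hit anywhere;
# else LINEAGE_SPECIFIC iff any lineage-non-focal hit anywhere; else
# SPECIES_SPECIFIC.  The cascade must compute the same function.
oracle_scope_rule <- function(genes, evidence, config) {
  scope_of_stage <- setNames(
    vapply(config$stages, function(s) s$source$scope, character(1)),
    vapply(config$stages, function(s) s$source$name, character(1)))
  phase_of_stage <- setNames(
    vapply(config$stages, function(s) s$source$phase, character(1)),
    names(scope_of_stage))
  nl <- character(0); lnf <- character(0)
  for (nm in names(evidence)) {
    tab <- as.data.frame(evidence[[nm]])
    tab <- tab[tab$evalue < config$evalue_threshold, , drop = FALSE]
    if (!nrow(tab)) next
    if (phase_of_stage[[nm]] == "candidate") {
      scopes <- rep(scope_of_stage[[nm]], nrow(tab))
    } else {
      scopes <- rep(NA_character_, nrow(tab))
      for (pat in names(config$scope_map)) {
        m <- is.na(scopes) & grepl(pat, tab$subject_id)
        scopes[m] <- config$scope_map[[pat]]
      }
    }
    nl <- union(nl, tab$query_id[scopes == "non_lineage"])
    lnf <- union(lnf, tab$query_id[scopes == "lineage_non_focal"])
  }
  ifelse(genes %in% nl, "CONSERVED",
         ifelse(genes %in% lnf, "LINEAGE_SPECIFIC", "SPECIES_SPECIFIC"))
}

# random small cascade instance generator for the order-equivalence property
random_cascade_instance <- function(n_genes = 20) {
  genes <- sprintf("g%02d", seq_len(n_genes))
  config <- default_cascade_config()
  evidence <- list()
  for (st in config$stages) {
    nm <- st$source$name
    n_hits <- sample(0:n_genes, 1L)
    if (!n_hits) next
    qs <- sample(genes, n_hits, replace = TRUE)
    prefix <- if (st$source$phase == "candidate") {
      if (st$source$scope == "non_lineage") "NL|" else "LNF|"
    } else sample(c("NL|", "LNF|", "FOC|"), n_hits, replace = TRUE)
    evidence[[nm]] <- hit_table(data.frame(
      query_id = qs, subject_id = paste0(prefix, "s", seq_len(n_hits)),
      source = nm, pident = 90, length = 50L, mismatch = 5L, gapopen = 0L,
      qstart = 1L, qend = 50L, sstart = 1L, send = 50L,
      evalue = 10^runif(n_hits, -20, 0), bitscore = 100,
      stringsAsFactors = FALSE), sources = nm)
  }
  list(genes = genes, evidence = evidence, config = config)
}

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
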