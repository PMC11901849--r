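# Per-gene structural features and the class contrasts used to characterize
# orphan vs lineage-specific vs conserved gene sets.

#' GC percentage of sequences
#'
#' `100 * (G + C) / (A + C + G + T)`; ambiguity codes are excluded from both
#' numerator and denominator.  Returns `NA` for sequences with no unambiguous
#' base (and for empty strings), never 0 by convention.
#'
#' @param seqs Character vector of nucleotide sequences.
#' @return Numeric vector of GC percentages in `[0, 100]` or `NA`.
#' @export
gc_percent <- function(seqs) {
  out <- rep(NA_real_, length(seqs))
  ok <- nzchar(seqs) & !is.na(seqs)
  if (any(ok)) {
    set <- Biostrings::DNAStringSet(chartr("U", "T", seqs[ok]))
    freq <- Biostrings::letterFrequency(set, c("A", "C", "G", "T"))
    denom <- rowSums(freq)
    gc <- 100 * (freq[, "G"] + freq[, "C"]) / denom
    gc[denom == 0] <- NA_real_
    out[ok] <- gc
  }
  out
}

intron_intervals <- function(gene, exons) {
  ex <- exons[exons$gene_id == gene, , drop = FALSE]
  if (nrow(ex) < 2L) return(ex[0L, c("start", "end")])
  data.frame(start = ex$end[-nrow(ex)] + 1L, end = ex$start[-1L] - 1L)
}

#' Compute per-gene structural features
#'
#' For every gene model: protein/CDS/gene length, total intron length, exon
#' count, and GC content of the CDS footprint, the intron footprint, and the
#' full gene span.  GC is strand-independent (complement-invariant), so
#' sequences are read from the plus strand regardless of gene orientation.
#' `gc_intron` is `NA` exactly when the gene has no intron sequence.
#'
#' @param models A [gene_models] object.
#' @param genome Chromosome sequences: a nucleotide [seq_records] or a named
#'   character vector / `DNAStringSet` covering every model coordinate.
#' @return Data frame with one row per gene: `gene_id`, `protein_length`,
#'   `cds_length`, `gene_length`, `intron_length_total`, `n_exons`,
#'   `gc_cds`, `gc_intron`, `gc_gene`, `intron_length_mean`.
#' @export
compute_features <- function(models, genome) {
  stopifnot(inherits(models, "gene_models"))
  chrom <- genome_as_character(genome)
  g <- models$genes
  missing_chr <- setdiff(unique(g$chromosome), names(chrom))
  if (length(missing_chr)) {
    stop("chromosome(s) absent from genome: ",
         paste(missing_chr, collapse = ", "))
  }
  beyond <- g$end > nchar(chrom[g$chromosome])
  if (any(beyond)) {
    stop("gene coordinates beyond sequence end: ",
         paste(g$gene_id[beyond], collapse = ", "))
  }
  footprint_seq <- function(gid, iv) {
    if (!nrow(iv)) return("")
    chr <- chrom[[g$chromosome[match(gid, g$gene_id)]]]
    paste(substring(chr, iv$start, iv$end), collapse = "")
  }
  cds_seq <- vapply(g$gene_id, function(gid)
    footprint_seq(gid, models$cds[models$cds$gene_id == gid, , drop = FALSE]),
    character(1))
  intron_seq <- vapply(g$gene_id, function(gid)
    footprint_seq(gid, intron_intervals(gid, models$exons)), character(1))
  gene_seq <- substring(chrom[g$chromosome], g$start, g$end)
  n_introns <- pmax(g$n_exons - 1L, 0L)
  data.frame(
    gene_id = g$gene_id,
    protein_length = g$protein_length,
    cds_length = g$cds_length,
    gene_length = g$gene_length,
    intron_length_total = g$intron_length_total,
    n_exons = g$n_exons,
    gc_cds = gc_percent(cds_seq),
    gc_intron = gc_percent(intron_seq),
    gc_gene = gc_percent(gene_seq),
    intron_length_mean = ifelse(n_introns > 0,
                                g$intron_length_total / n_introns, NA_real_),
    stringsAsFactors = FALSE, row.names = NULL)
}

genome_as_character <- function(genome) {
  if (inherits(genome, "seq_records")) {
    if (any(genome$kind != "nucleotide")) stop("genome must be nucleotide")
    return(setNames(genome$seq, genome$id))
  }
  if (inherits(genome, "DNAStringSet") || inherits(genome, "XStringSet")) {
    return(setNames(as.character(genome), names(genome)))
  }
  if (is.character(genome) && !is.null(names(genome))) return(toupper(genome))
  stop("genome must be seq_records, DNAStringSet or a named character vector")
}

#' Per-class feature summaries (mean, SD, n)
#'
#' Summarizes every numeric feature column per class with the mean and sample
#' standard deviation (denominator n - 1); undefined values are excluded
#' pairwise and the contributing `n` is reported.  Classes with `n < 2`
#' defined values get `sd = NA` and are flagged in the `sd_defined` column.
#'
#' @param features Output of [compute_features()].
#' @param labels Named character vector `gene_id -> class`, or a data frame
#'   with `gene_id` and `label` columns.
#' @return Long data frame: `label`, `feature`, `mean`, `sd`, `n`,
#'   `sd_defined`.
#' @export
summarize_by_class <- function(features, labels) {
  labels <- as_label_vector(labels)
  if (!all(features$gene_id %in% names(labels))) {
    stop("every feature row needs a class label")
  }
  cls <- labels[features$gene_id]
  num_cols <- setdiff(names(features)[vapply(features, is.numeric, logical(1))],
                      character(0))
  out <- list()
  for (lv in unique(cls)) {
    rows <- features[cls == lv, , drop = FALSE]
    for (col in num_cols) {
      v <- rows[[col]]
      v <- v[!is.na(v)]
      out[[length(out) + 1L]] <- data.frame(
        label = lv, feature = col,
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) >= 2L) sd(v) else NA_real_,
        n = length(v), sd_defined = length(v) >= 2L,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

as_label_vector <- function(labels) {
  if (inherits(labels, "classification_result")) labels <- labels$labels
  if (is.data.frame(labels)) {
    stopifnot(all(c("gene_id", "label") %in% names(labels)))
    return(setNames(labels$label, labels$gene_id))
  }
  if (is.character(labels) && !is.null(names(labels))) return(labels)
  stop("labels must be a named vector, data frame or classification_result")
}

#' One-way ANOVA
#'
#' Classical between/within variance decomposition; p from the F distribution
#' on (k - 1, N - k) degrees of freedom.  When every observation is identical
#' (zero between- and within-group variance) F is defined as 0 with p = 1.
#'
#' @param groups List of at least two numeric vectors (each non-empty), or a
#'   data frame with `value` and `group` columns.
#' @return List with `F`, `p`, `df` (numerator, denominator).
#' @export
one_way_anova <- function(groups) {
  if (is.data.frame(groups)) {
    groups <- split(groups$value, groups$group)
  }
  k <- length(groups)
  if (k < 2L) stop("need at least two groups")
  n <- lengths(groups)
  if (any(n < 1L)) stop("every group needs at least one observation")
  N <- sum(n)
  if (N - k < 1L) stop("no residual degrees of freedom (total n must exceed ",
                       "the number of groups)")
  values <- unlist(groups, use.names = FALSE)
  if (var(values) == 0) {
    return(list(F = 0, p = 1, df = c(k - 1L, N - k)))
  }
  grand <- mean(values)
  ssb <- sum(n * (vapply(groups, mean, numeric(1)) - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  Fst <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = Fst, p = stats::pf(Fst, k - 1, N - k, lower.tail = FALSE),
       df = c(k - 1L, N - k))
}

#' Bin genes by intron count
#'
#' Intron count is `n_exons - 1`, binned into the six standard categories
#' (intron-less, 1, 2, 3, 4, and 5-or-more introns); counts and percentages
#' are reported per class, percentages summing to 100 within each class.
#'
#' @param features Output of [compute_features()] (needs `gene_id`,
#'   `n_exons`).
#' @param labels As in [summarize_by_class()].
#' @return Data frame: `label`, `bin`, `count`, `percent`.
#' @export
bin_introns <- function(features, labels) {
  labels <- as_label_vector(labels)
  if (!all(features$gene_id %in% names(labels))) {
    stop("every gene needs a class label")
  }
  stopifnot(all(features$n_exons >= 1L))
  n_intron <- features$n_exons - 1L
  bins <- c("0", "1", "2", "3", "4", ">=5")
  bin <- factor(ifelse(n_intron >= 5L, ">=5", as.character(n_intron)),
                levels = bins)
  cls <- labels[features$gene_id]
  out <- list()
  for (lv in unique(cls)) {
    tab <- table(bin[cls == lv])
    out[[length(out) + 1L]] <- data.frame(
      label = lv, bin = bins, count = as.integer(tab),
      percent = 100 * as.integer(tab) / sum(tab),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Chromosome distribution and physical map of a gene class
#'
#' Per chromosome: number of class genes, number of all genes, and the class
#' percentage `100 * class / all` on that chromosome.  Genes on sequences not
#' listed in `chrom_lengths` go to an `"unplaced"` bucket (scaffold genes)
#' when `allow_unplaced` is `TRUE`, else raise an error.  The physical map
#' lists the class genes as `(chromosome, start, gene_id)` sorted by
#' position.
#'
#' @param labels As in [summarize_by_class()].
#' @param models A [gene_models] object covering the labelled genes.
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param class Class whose distribution is computed; default
#'   `"SPECIES_SPECIFIC"`.
#' @param allow_unplaced Collect genes on unknown sequences into an
#'   `"unplaced"` bucket instead of failing.
#' @return List with `distribution` (chromosome, length, n_class_genes,
#'   n_all_genes, percent), `physical_map`, and `unplaced` (data frame of
#'   unplaced class genes).
#' @export
chrom_distribution <- function(labels, models, chrom_lengths,
                               class = "SPECIES_SPECIFIC",
                               allow_unplaced = TRUE) {
  labels <- as_label_vector(labels)
  g <- models$genes
  if (!all(g$gene_id %in% names(labels))) stop("every gene needs a label")
  placed <- g$chromosome %in% names(chrom_lengths)
  if (!allow_unplaced && any(!placed)) {
    stop("gene(s) on unknown chromosome(s): ",
         paste(unique(g$chromosome[!placed]), collapse = ", "))
  }
  cls <- labels[g$gene_id] == class
  dist <- data.frame(chromosome = names(chrom_lengths),
                     length = as.numeric(chrom_lengths),
                     stringsAsFactors = FALSE)
  dist$n_class_genes <- vapply(dist$chromosome, function(ch)
    sum(g$chromosome == ch & cls), integer(1))
  dist$n_all_genes <- vapply(dist$chromosome, function(ch)
    sum(g$chromosome == ch), integer(1))
  dist$percent <- ifelse(dist$n_all_genes > 0,
                         100 * dist$n_class_genes / dist$n_all_genes, NA_real_)
  pm <- g[cls & placed, c("chromosome", "start", "gene_id"), drop = FALSE]
  pm <- pm[order(pm$chromosome, pm$start), , drop = FALSE]
  rownames(pm) <- NULL
  unpl <- g[cls & !placed, c("chromosome", "start", "gene_id"), drop = FALSE]
  rownames(unpl) <- NULL
  list(distribution = dist, physical_map = pm, unplaced = unpl)
}

#' Spearman rank correlation with t-approximation or exact permutation p
#'
#' Rho is the Pearson correlation of average ranks (tie-safe).  The default
#' two-sided p uses the t approximation `t = rho * sqrt((n-2)/(1-rho^2))` on
#' n - 2 degrees of freedom; for n <= 9 an exact permutation p (enumeration
#' of all n! rank assignments) is available.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param p_method `"t"` (default) or `"exact"` (n <= 9 only).
#' @return List with `rho`, `p`, `n`, `method`.
#' @export
spearman_test <- function(x, y, p_method = c("t", "exact")) {
  p_method <- match.arg(p_method)
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (var(x) == 0 || var(y) == 0) {
    warning("constant vector: Spearman's rho is undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n, method = p_method))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (p_method == "exact") {
    if (n > 9L) stop("exact permutation p available only for n <= 9")
    perms <- permutations_of(n)
    ryp <- matrix(ry[perms], nrow = nrow(perms))
    num <- ryp %*% rx - n * mean(rx) * mean(ry)
    rho_perm <- as.numeric(num) / ((n - 1) * sd(rx) * sd(ry))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), n - 2)
    }
  }
  list(rho = rho, p = p, n = n, method = p_method)
}

# all permutations of 1..n as an n! x n integer matrix
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub, n)[, append(seq_len(n - 1L), n, after = pos - 1L),
                           drop = FALSE]
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}
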