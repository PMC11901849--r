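#' Gene model collections
#'
#' A `gene_models` object bundles one representative gene model per gene:
#' a `genes` data frame (gene_id, chromosome, strand, start, end,
#' transcript_id, cds_length, gene_length, intron_length_total, n_exons,
#' protein_length) plus `exons` and `cds` interval data frames (gene_id,
#' start, end; 1-based inclusive, sorted, non-overlapping).
#'
#' @param genes,exons,cds Data frames as described above (`genes` needs
#'   gene_id, chromosome, strand, start, end; derived columns are computed).
#' @param protein_length Optional named vector of protein lengths; when
#'   absent it is derived from the CDS length (see `stop_codon_included`).
#' @param stop_codon_included Logical; when `TRUE` (default) the annotated
#'   CDS includes the stop codon and `protein_length = cds_length/3 - 1`,
#'   otherwise `cds_length/3`.
#' @return A list of class `gene_models`.
#' @export
gene_models <- function(genes, exons, cds, protein_length = NULL,
                        stop_codon_included = TRUE) {
  stopifnot(all(c("gene_id", "chromosome", "strand", "start", "end") %in%
                  names(genes)))
  if (any(genes$end < genes$start)) stop("gene span end < start")
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  exons <- exons[order(exons$gene_id, exons$start), , drop = FALSE]
  cds <- cds[order(cds$gene_id, cds$start), , drop = FALSE]
  for (gid in genes$gene_id) {
    g <- genes[genes$gene_id == gid, ]
    ex <- exons[exons$gene_id == gid, , drop = FALSE]
    if (!nrow(ex)) stop("gene ", gid, " has no exons")
    if (any(ex$start < g$start | ex$end > g$end)) {
      stop("exon outside gene span for gene ", gid)
    }
    if (nrow(ex) > 1L && any(ex$start[-1L] <= ex$end[-nrow(ex)])) {
      stop("overlapping exons for gene ", gid)
    }
    cd <- cds[cds$gene_id == gid, , drop = FALSE]
    if (nrow(cd)) {
      inside <- vapply(seq_len(nrow(cd)), function(i) {
        any(cd$start[i] >= ex$start & cd$end[i] <= ex$end)
      }, logical(1))
      if (!all(inside)) stop("CDS outside exon footprint for gene ", gid)
    }
  }
  exl <- tapply(exons$end - exons$start + 1L, exons$gene_id, sum)
  cdl <- tapply(cds$end - cds$start + 1L, cds$gene_id, sum)
  nex <- tapply(exons$gene_id, exons$gene_id, length)
  genes$gene_length <- genes$end - genes$start + 1L
  genes$n_exons <- as.integer(nex[genes$gene_id])
  genes$intron_length_total <-
    genes$gene_length - as.integer(exl[genes$gene_id])
  genes$cds_length <- as.integer(cdl[genes$gene_id])
  genes$cds_length[is.na(genes$cds_length)] <- 0L
  if (is.null(protein_length)) {
    bad <- genes$cds_length %% 3L != 0L
    if (any(bad)) {
      warning("CDS length not a multiple of 3 for gene(s) ",
              paste(genes$gene_id[bad], collapse = ", "),
              "; protein length floor-divided")
    }
    genes$protein_length <-
      genes$cds_length %/% 3L - as.integer(stop_codon_included)
    genes$protein_length <- pmax(genes$protein_length, 0L)
  } else {
    genes$protein_length <- as.integer(protein_length[genes$gene_id])
  }
  if (!"transcript_id" %in% names(genes)) genes$transcript_id <- NA_character_
  rownames(genes) <- rownames(exons) <- rownames(cds) <- NULL
  structure(list(genes = genes, exons = exons, cds = cds),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes on",
      length(unique(x$genes$chromosome)), "sequence(s)\n")
  invisible(x)
}

#' Parse gene models from a GFF3 file
#'
#' Reads `gene`/`mRNA`/`exon`/`CDS` features (1-based inclusive coordinates)
#' and keeps one representative isoform per gene: the mRNA with the longest
#' total CDS, ties broken by the lexicographically smallest transcript id.
#'
#' @param path Path to a GFF3 file.
#' @param stop_codon_included Passed to [gene_models()]; default `TRUE`
#'   (annotated CDS includes the stop codon).
#' @return A [gene_models] object.
#' @export
parse_gff <- function(path, stop_codon_included = TRUE) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$Parent <- vapply(S4Vectors::mcols(gr)$Parent, function(p)
    if (length(p)) as.character(p[1L]) else NA_character_, character(1))
  gene_rows <- df[df$type == "gene", , drop = FALSE]
  if (!nrow(gene_rows)) stop("no gene features in ", path)
  mrna <- df[df$type == "mRNA", , drop = FALSE]
  exon <- df[df$type == "exon", , drop = FALSE]
  cds <- df[df$type == "CDS", , drop = FALSE]
  cds_total <- tapply(cds$end - cds$start + 1L, cds$Parent, sum)
  # representative isoform per gene: longest total CDS, tie -> smallest id
  mrna$cds_total <- ifelse(mrna$ID %in% names(cds_total),
                           cds_total[mrna$ID], 0L)
  mrna <- mrna[order(mrna$Parent, -mrna$cds_total, mrna$ID), , drop = FALSE]
  rep_mrna <- mrna[!duplicated(mrna$Parent), , drop = FALSE]
  keep_tx <- setNames(rep_mrna$ID, rep_mrna$Parent)
  genes <- data.frame(gene_id = gene_rows$ID,
                      chromosome = as.character(gene_rows$seqnames),
                      strand = as.character(gene_rows$strand),
                      start = gene_rows$start, end = gene_rows$end,
                      transcript_id = unname(keep_tx[gene_rows$ID]),
                      stringsAsFactors = FALSE)
  if (anyNA(genes$transcript_id)) {
    stop("gene(s) without mRNA isoform in ", path, ": ",
         paste(genes$gene_id[is.na(genes$transcript_id)], collapse = ", "))
  }
  tx2gene <- setNames(rep_mrna$Parent, rep_mrna$ID)
  exon <- exon[exon$Parent %in% rep_mrna$ID, , drop = FALSE]
  cds <- cds[cds$Parent %in% rep_mrna$ID, , drop = FALSE]
  exons_df <- data.frame(gene_id = unname(tx2gene[exon$Parent]),
                         start = exon$start, end = exon$end,
                         stringsAsFactors = FALSE)
  cds_df <- data.frame(gene_id = unname(tx2gene[cds$Parent]),
                       start = cds$start, end = cds$end,
                       stringsAsFactors = FALSE)
  gene_models(genes, exons_df, cds_df,
              stop_codon_included = stop_codon_included)
}

#' Write gene models as GFF3
#'
#' @param models A [gene_models] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(models, path) {
  g <- models$genes
  tx <- ifelse(is.na(g$transcript_id), paste0(g$gene_id, ".t1"),
               g$transcript_id)
  rows <- list(
    GenomicRanges::GRanges(g$chromosome,
                           IRanges::IRanges(g$start, g$end), g$strand,
                           type = "gene", ID = g$gene_id,
                           Parent = NA_character_, phase = NA_integer_),
    GenomicRanges::GRanges(g$chromosome,
                           IRanges::IRanges(g$start, g$end), g$strand,
                           type = "mRNA", ID = tx, Parent = g$gene_id,
                           phase = NA_integer_))
  tx_of <- setNames(tx, g$gene_id)
  chr_of <- setNames(g$chromosome, g$gene_id)
  str_of <- setNames(g$strand, g$gene_id)
  if (nrow(models$exons)) {
    d <- models$exons
    rows[[length(rows) + 1L]] <- GenomicRanges::GRanges(
      chr_of[d$gene_id], IRanges::IRanges(d$start, d$end), str_of[d$gene_id],
      type = "exon", ID = NA_character_, Parent = unname(tx_of[d$gene_id]),
      phase = NA_integer_)
  }
  if (nrow(models$cds)) {
    d <- models$cds
    # phase: codon offset at the start of each CDS piece, in translation order
    d$phase <- NA_integer_
    for (gid in unique(d$gene_id)) {
      idx <- which(d$gene_id == gid)
      idx <- idx[order(d$start[idx],
                       decreasing = str_of[[gid]] == "-")]
      lens <- d$end[idx] - d$start[idx] + 1L
      d$phase[idx] <- as.integer((3L - cumsum(c(0L, lens[-length(lens)])) %% 3L)
                                 %% 3L)
    }
    rows[[length(rows) + 1L]] <- GenomicRanges::GRanges(
      chr_of[d$gene_id], IRanges::IRanges(d$start, d$end), str_of[d$gene_id],
      type = "CDS", ID = NA_character_, Parent = unname(tx_of[d$gene_id]),
      phase = d$phase)
  }
  gr <- suppressWarnings(do.call(c, rows))
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
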