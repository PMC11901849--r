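# FPKM expression matrices and specificity calls (tissue-/stage-unique genes,
# Venn partitions, cross-design intersections).

#' Load an FPKM expression matrix with its sample design
#'
#' The TSV must have gene ids in the first column and one column per sample;
#' every sample must map to exactly one group in the design.
#'
#' @param path TSV path (header row with sample names).
#' @param design Data frame with `sample` and `group` columns, or a named
#'   character vector `sample -> group`.
#' @return A numeric matrix (genes x samples) of class `expression_matrix`
#'   with a `design` attribute (named vector `sample -> group`).
#' @export
load_expression <- function(path, design) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) stop("empty expression matrix")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate gene id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  expression_matrix(m, design)
}

#' Construct an expression matrix from values and a design
#'
#' @param m Numeric genes x samples matrix (non-negative, dimnames set).
#' @param design As in [load_expression()].
#' @return An `expression_matrix`.
#' @export
expression_matrix <- function(m, design) {
  if (is.data.frame(design)) {
    stopifnot(all(c("sample", "group") %in% names(design)))
    design <- setNames(as.character(design$group), design$sample)
  }
  if (anyNA(m)) stop("missing values in expression matrix")
  if (any(m < 0)) stop("negative FPKM value(s)")
  unmapped <- setdiff(colnames(m), names(design))
  if (length(unmapped)) {
    stop("sample(s) absent from design: ", paste(unmapped, collapse = ", "))
  }
  structure(m, design = design[colnames(m)], class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  d <- attr(x, "design")
  cat("expression_matrix:", nrow(x), "genes x", ncol(x), "samples in",
      length(unique(d)), "groups\n")
  invisible(x)
}

#' Genes with expression evidence
#'
#' A gene counts as expressed when any sample exceeds the floor (strictly;
#' the default floor of 0 implements the `FPKM > 0 in at least one sample`
#' rule).
#'
#' @param matrix An `expression_matrix`.
#' @param floor Expression floor; strict `>` comparison. Default 0.
#' @return Character vector of expressed gene ids.
#' @export
expressed_genes <- function(matrix, floor = 0) {
  stopifnot(inherits(matrix, "expression_matrix"))
  rownames(matrix)[apply(unclass(matrix) > floor, 1L, any)]
}

group_expressed <- function(matrix, floor = 0, collapse = c("any", "mean")) {
  collapse <- match.arg(collapse)
  design <- attr(matrix, "design")
  groups <- unique(design)
  m <- unclass(matrix)
  out <- sapply(groups, function(g) {
    sub <- m[, design == g, drop = FALSE]
    if (collapse == "any") apply(sub > floor, 1L, any)
    else rowMeans(sub) > floor
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(m),
                                       dimnames = list(rownames(m), groups))
  out
}

#' Venn partition of expressed genes across groups
#'
#' Group-level expression is "any sample of the group above the floor"
#' (`collapse = "any"`, the default) or "group mean above the floor".  Counts
#' are reported for every non-empty subset of groups and sum to the number of
#' expressed genes; per-gene specificity calls (`not_expressed`, `unique`,
#' `shared`) are attached.
#'
#' @param matrix An `expression_matrix` with 2-6 groups.
#' @param floor Expression floor (strict `>`), default 0.
#' @param collapse `"any"` (default) or `"mean"` replicate collapsing.
#' @return List with `counts` (data frame: `subset` as `a&b` strings, `count`)
#'   and `calls` (data frame: `gene_id`, `expressed_groups`, `status`).
#' @export
venn_partition <- function(matrix, floor = 0, collapse = c("any", "mean")) {
  stopifnot(inherits(matrix, "expression_matrix"))
  ge <- group_expressed(matrix, floor, match.arg(collapse))
  groups <- colnames(ge)
  if (length(groups) < 2L || length(groups) > 6L) {
    stop("venn_partition supports 2 to 6 groups; got ", length(groups))
  }
  membership <- apply(ge, 1L, function(r) paste(groups[r], collapse = "&"))
  n_on <- rowSums(ge)
  calls <- data.frame(
    gene_id = rownames(ge),
    expressed_groups = membership,
    status = ifelse(n_on == 0L, "not_expressed",
                    ifelse(n_on == 1L, "unique", "shared")),
    stringsAsFactors = FALSE, row.names = NULL)
  subsets <- unlist(lapply(seq_along(groups), function(k)
    utils::combn(groups, k, paste, collapse = "&")))
  counts <- data.frame(subset = subsets,
                       count = as.integer(table(factor(
                         membership[n_on > 0L], levels = subsets))),
                       stringsAsFactors = FALSE)
  list(counts = counts, calls = calls)
}

#' Genes uniquely expressed in a single group
#'
#' @param calls The `calls` element of [venn_partition()].
#' @return Character vector of gene ids with `status == "unique"`.
#' @export
unique_genes <- function(calls) calls$gene_id[calls$status == "unique"]

#' Genes specific in two independent designs
#'
#' Returns the genes called `unique` in both call sets (e.g. unique to one
#' tissue AND unique to one growth stage).
#'
#' @param calls_a,calls_b `calls` data frames from [venn_partition()] over
#'   the same gene universe.
#' @return Character vector of gene ids.
#' @export
intersect_specific <- function(calls_a, calls_b) {
  intersect(unique_genes(calls_a), unique_genes(calls_b))
}
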