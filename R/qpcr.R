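# Relative qPCR expression by the 2^-ddCt method, with one-way ANOVA and
# Tukey-HSD compact letter displays for the group comparisons.

#' Validate a qPCR Ct table
#'
#' @param table Data frame with columns `gene`, `group`, `replicate`,
#'   `ct_target`, `ct_reference` (one row per technical measurement).
#' @param calibrator Calibrator group name (e.g. the untreated control);
#'   must be present for every gene.
#' @return The validated table of class `qpcr_table` with a `calibrator`
#'   attribute.
#' @export
qpcr_table <- function(table, calibrator) {
  need <- c("gene", "group", "replicate", "ct_target", "ct_reference")
  stopifnot(all(need %in% names(table)))
  if (any(table$ct_target <= 0) || any(table$ct_reference <= 0)) {
    stop("Ct values must be positive")
  }
  miss <- setdiff(unique(table$gene),
                  unique(table$gene[table$group == calibrator]))
  if (length(miss)) {
    stop("calibrator group '", calibrator, "' missing for gene(s): ",
         paste(miss, collapse = ", "))
  }
  structure(as.data.frame(table), calibrator = calibrator,
            class = c("qpcr_table", "data.frame"))
}

#' Relative expression by the 2^-ddCt method
#'
#' Per replicate, `dCt = ct_target - ct_reference` (normalization to the
#' reference gene, e.g. Actin); `ddCt = dCt - mean dCt of the gene's
#' calibrator group`; `fold = 2^-ddCt`.  Group means and standard errors are
#' computed over replicate folds, so the calibrator group's mean ddCt is 0 by
#' construction (its mean fold is 1 only up to replicate noise, since the
#' mean of `2^-x` is not `2^-mean(x)`).
#'
#' @param table A [qpcr_table] (or a data frame plus `calibrator`).
#' @param calibrator Calibrator group; defaults to the table's attribute.
#' @return List of class `relative_expression` with `replicates` (per-row
#'   `dct`, `ddct`, `fold`) and `summary` (per gene x group: `mean_fold`,
#'   `se_fold`, `n`); `se_fold` is `NA` when a group has a single replicate.
#' @export
delta_delta_ct <- function(table, calibrator = NULL) {
  if (!inherits(table, "qpcr_table")) {
    if (is.null(calibrator)) stop("'calibrator' required")
    table <- qpcr_table(table, calibrator)
  }
  calibrator <- attr(table, "calibrator", exact = TRUE)
  df <- as.data.frame(table)
  df$dct <- df$ct_target - df$ct_reference
  cal_mean <- tapply(df$dct[df$group == calibrator],
                     df$gene[df$group == calibrator], mean)
  df$ddct <- df$dct - cal_mean[df$gene]
  df$fold <- 2^(-df$ddct)
  agg <- aggregate(fold ~ gene + group, df, function(v)
    c(mean = mean(v), se = if (length(v) >= 2L) sd(v) / sqrt(length(v))
      else NA_real_, n = length(v)))
  summary <- data.frame(gene = agg$gene, group = agg$group,
                        mean_fold = agg$fold[, "mean"],
                        se_fold = agg$fold[, "se"],
                        n = as.integer(agg$fold[, "n"]),
                        stringsAsFactors = FALSE)
  if (any(summary$n < 2L)) {
    warning("single-replicate group(s): standard error undefined")
  }
  structure(list(replicates = df, summary = summary,
                 calibrator = calibrator),
            class = "relative_expression")
}

#' @export
print.relative_expression <- function(x, ...) {
  cat("relative_expression:", length(unique(x$summary$gene)), "gene(s),",
      length(unique(x$summary$group)), "groups (calibrator:",
      x$calibrator, ")\n")
  invisible(x)
}

#' Compact letter display from pairwise significance decisions
#'
#' Standard insert-and-absorb algorithm: start from one letter covering all
#' groups; for every significantly different pair sharing a letter, split
#' that letter column; absorb columns that became subsets of others.  Groups
#' sharing no letter differ significantly.
#'
#' @param groups Character vector of group names, in display order (letters
#'   are assigned left to right in this order).
#' @param different Logical matrix (`groups` x `groups`): `TRUE` where the
#'   pair is significantly different.
#' @return Named character vector of letter strings per group.
#' @export
compact_letters <- function(groups, different) {
  cols <- list(setNames(rep(TRUE, length(groups)), groups))
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      if (j <= i || !different[groups[i], groups[j]]) next
      for (ci in seq_along(cols)) {
        col <- cols[[ci]]
        if (col[groups[i]] && col[groups[j]]) {
          a <- col; a[groups[i]] <- FALSE
          b <- col; b[groups[j]] <- FALSE
          cols[[ci]] <- a
          cols[[length(cols) + 1L]] <- b
        }
      }
      # absorb columns that are subsets of another column
      keep <- rep(TRUE, length(cols))
      for (u in seq_along(cols)) {
        for (v in seq_along(cols)) {
          if (u != v && keep[u] && keep[v] &&
              all(cols[[v]] | !cols[[u]]) && any(cols[[v]] & !cols[[u]])) {
            keep[u] <- FALSE
          }
        }
      }
      # drop exact duplicates too
      sig <- vapply(cols, function(c) paste(c, collapse = ""), character(1))
      keep <- keep & !duplicated(sig)
      cols <- cols[keep]
    }
  }
  # order letter columns by first group they contain
  first <- vapply(cols, function(c) which(c)[1L], integer(1))
  cols <- cols[order(first)]
  letters_used <- letters[seq_along(cols)]
  out <- vapply(groups, function(g) {
    paste(letters_used[vapply(cols, function(c) c[[g]], logical(1))],
          collapse = "")
  }, character(1))
  setNames(out, groups)
}

#' ANOVA with Tukey-HSD letter groups for relative expression
#'
#' Per gene: one-way ANOVA of replicate fold values across groups, then all
#' pairwise comparisons by Tukey's HSD at the given alpha; groups are
#' labelled with a compact letter display (groups sharing no letter differ
#' significantly at `alpha`).  Degenerate all-equal data yields a single
#' shared letter.
#'
#' @param rel A `relative_expression` from [delta_delta_ct()], or a data
#'   frame with `gene`, `group`, `fold` replicate rows.
#' @param alpha Family-wise significance level, default 0.05.
#' @return Data frame: `gene`, `group`, `mean_fold`, `letters`, `anova_f`,
#'   `anova_p`.
#' @export
anova_letters <- function(rel, alpha = 0.05) {
  df <- if (inherits(rel, "relative_expression")) rel$replicates else rel
  stopifnot(all(c("gene", "group", "fold") %in% names(df)))
  out <- list()
  for (g in unique(df$gene)) {
    d <- df[df$gene == g, , drop = FALSE]
    groups <- unique(d$group)
    n <- table(d$group)
    if (length(groups) < 2L || any(n < 2L)) {
      stop("gene ", g, ": need >= 2 groups with >= 2 replicates each")
    }
    means <- tapply(d$fold, d$group, mean)[groups]
    if (var(d$fold) == 0) {
      lets <- setNames(rep("a", length(groups)), groups)
      fstat <- 0; pval <- 1
    } else {
      d$group <- factor(d$group, levels = groups)
      fit <- aov(fold ~ group, data = d)
      an <- summary(fit)[[1L]]
      fstat <- an[["F value"]][1L]; pval <- an[["Pr(>F)"]][1L]
      tk <- TukeyHSD(fit, conf.level = 1 - alpha)$group
      diffmat <- matrix(FALSE, length(groups), length(groups),
                        dimnames = list(groups, groups))
      pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
      for (i in seq_along(pairs)) {
        a <- pairs[[i]][1L]; b <- pairs[[i]][2L]
        sig <- tk[i, "p adj"] < alpha
        diffmat[a, b] <- diffmat[b, a] <- isTRUE(sig)
      }
      ord <- groups[order(-means)]
      lets <- compact_letters(ord, diffmat)[groups]
    }
    out[[length(out) + 1L]] <- data.frame(
      gene = g, group = groups, mean_fold = as.numeric(means),
      letters = unname(lets), anova_f = fstat, anova_p = pval,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
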