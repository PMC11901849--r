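gff_lines <- function(rows) {
  c("##gff-version 3", vapply(rows, function(r) paste(r, collapse = "\t"),
                              character(1)))
}

test_that("parse_gff builds gene models with intron arithmetic", {
  f <- write_tmp(gff_lines(list(
    c("chr1", "sim", "gene", 1, 300, ".", "+", ".", "ID=gA"),
    c("chr1", "sim", "mRNA", 1, 300, ".", "+", ".", "ID=gA.t1;Parent=gA"),
    c("chr1", "sim", "exon", 1, 300, ".", "+", ".", "Parent=gA.t1"),
    c("chr1", "sim", "CDS", 1, 300, ".", "+", ".", "Parent=gA.t1"),
    c("chr1", "sim", "gene", 401, 701, ".", "-", ".", "ID=gB"),
    c("chr1", "sim", "mRNA", 401, 701, ".", "-", ".", "ID=gB.t1;Parent=gB"),
    c("chr1", "sim", "exon", 401, 500, ".", "-", ".", "Parent=gB.t1"),
    c("chr1", "sim", "exon", 601, 701, ".", "-", ".", "Parent=gB.t1"),
    c("chr1", "sim", "CDS", 401, 500, ".", "-", ".", "Parent=gB.t1"),
    c("chr1", "sim", "CDS", 601, 701, ".", "-", ".", "Parent=gB.t1"))), ".gff3")
  m <- parse_gff(f)
  gA <- m$genes[m$genes$gene_id == "gA", ]
  expect_equal(gA$gene_length, 300L)
  expect_equal(gA$n_exons, 1L)
  expect_equal(gA$intron_length_total, 0L)
  expect_equal(gA$protein_length, 99L)    # stop codon included by default
  gB <- m$genes[m$genes$gene_id == "gB", ]
  expect_equal(gB$n_exons, 2L)
  expect_equal(gB$intron_length_total, 100L)
  expect_equal(gB$cds_length, 201L)
  expect_equal(gB$protein_length, 66L)
})

test_that("the representative isoform is the one with the longest total CDS", {
  f <- write_tmp(gff_lines(list(
    c("chr1", "sim", "gene", 1, 600, ".", "+", ".", "ID=g1"),
    c("chr1", "sim", "mRNA", 1, 600, ".", "+", ".", "ID=g1.t2;Parent=g1"),
    c("chr1", "sim", "exon", 1, 600, ".", "+", ".", "Parent=g1.t2"),
    c("chr1", "sim", "CDS", 1, 300, ".", "+", ".", "Parent=g1.t2"),
    c("chr1", "sim", "mRNA", 1, 600, ".", "+", ".", "ID=g1.t1;Parent=g1"),
    c("chr1", "sim", "exon", 1, 600, ".", "+", ".", "Parent=g1.t1"),
    c("chr1", "sim", "CDS", 1, 150, ".", "+", ".", "Parent=g1.t1"))), ".gff3")
  m <- parse_gff(f)
  expect_equal(m$genes$transcript_id, "g1.t2")
  expect_equal(m$genes$cds_length, 300L)
})

test_that("parse_gff flags structural problems", {
  bad_exon <- write_tmp(gff_lines(list(
    c("chr1", "sim", "gene", 10, 100, ".", "+", ".", "ID=g1"),
    c("chr1", "sim", "mRNA", 10, 100, ".", "+", ".", "ID=g1.t1;Parent=g1"),
    c("chr1", "sim", "exon", 5, 100, ".", "+", ".", "Parent=g1.t1"),
    c("chr1", "sim", "CDS", 10, 100, ".", "+", ".", "Parent=g1.t1"))), ".gff3")
  expect_error(parse_gff(bad_exon), "exon outside gene span")

  not3 <- write_tmp(gff_lines(list(
    c("chr1", "sim", "gene", 1, 100, ".", "+", ".", "ID=g1"),
    c("chr1", "sim", "mRNA", 1, 100, ".", "+", ".", "ID=g1.t1;Parent=g1"),
    c("chr1", "sim", "exon", 1, 100, ".", "+", ".", "Parent=g1.t1"),
    c("chr1", "sim", "CDS", 1, 100, ".", "+", ".", "Parent=g1.t1"))), ".gff3")
  expect_warning(m <- parse_gff(not3), "not a multiple of 3")
  expect_equal(m$genes$protein_length, 100L %/% 3L - 1L)
})

test_that("GC content follows the unambiguous-base definition", {
  expect_equal(gc_percent("ATGC"), 50)
  expect_equal(gc_percent("NNNN"), NA_real_)
  expect_equal(gc_percent(""), NA_real_)
  expect_equal(gc_percent("GGCC"), 100)
  # GC is reverse-complement invariant
  set.seed(9)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 50, TRUE), collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(gc_percent(s), gc_percent(rc))
  }
})

test_that("compute_features on a toy gene matches hand counts", {
  genome <- seq_records("chr1", "GGGGATATCCCCNN", "nucleotide")
  genes <- data.frame(gene_id = "g1", chromosome = "chr1", strand = "+",
                      start = 1L, end = 12L, stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = "g1", start = c(1L, 9L), end = c(4L, 12L))
  m <- gene_models(genes, exons, exons, protein_length = c(g1 = 2L))
  ft <- compute_features(m, genome)
  expect_equal(ft$gc_cds, 100)
  expect_equal(ft$gc_intron, 0)
  expect_equal(ft$gc_gene, 100 * 8 / 12, tolerance = 1e-9)
  expect_equal(ft$gene_length, 12L)
  expect_equal(ft$intron_length_total, 4L)

  # all-N intron -> undefined, not zero
  genomeN <- seq_records("chr1", "GGGGNNNNCCCC", "nucleotide")
  ftN <- compute_features(m, genomeN)
  expect_true(is.na(ftN$gc_intron))

  # coordinates beyond the sequence end are an error
  genome_short <- seq_records("chr1", "GGGGATAT", "nucleotide")
  expect_error(compute_features(m, genome_short), "beyond sequence end")
})

test_that("gene length decomposes into exon and intron totals on simulations", {
  sim <- simulate_genomes(sim_genome_config(n_conserved = 6, n_lineage = 4,
                                            n_orphan = 4), seed = 21)
  ft <- compute_features(sim$models, sim$genome)
  exon_total <- tapply(sim$models$exons$end - sim$models$exons$start + 1L,
                       sim$models$exons$gene_id, sum)
  expect_equal(ft$gene_length,
               as.vector(exon_total[ft$gene_id]) + ft$intron_length_total)
  expect_true(all(ft$n_exons >= 1L))
})

test_that("summarize_by_class computes pairwise-complete means and SDs", {
  feats <- data.frame(gene_id = c("a", "b", "c"),
                      gene_length = c(100, 200, 50),
                      gc_intron = c(NA, 40, 60))
  labels <- c(a = "OG", b = "OG", c = "ECG")
  s <- summarize_by_class(feats, labels)
  og_len <- s[s$label == "OG" & s$feature == "gene_length", ]
  expect_equal(og_len$mean, 150)
  expect_equal(og_len$sd, sd(c(100, 200)))
  expect_equal(og_len$n, 2L)
  og_gc <- s[s$label == "OG" & s$feature == "gc_intron", ]
  expect_equal(og_gc$n, 1L)          # NA excluded pairwise
  expect_true(is.na(og_gc$sd) && !og_gc$sd_defined)
  ecg <- s[s$label == "ECG" & s$feature == "gene_length", ]
  expect_true(is.na(ecg$sd))
  expect_error(summarize_by_class(feats, c(a = "OG")), "label")
})

test_that("one-way ANOVA matches the closed-form decomposition", {
  r <- one_way_anova(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(r$F, 13.5)
  expect_equal(r$df, c(1L, 4L))
  expect_equal(r$p, stats::pf(13.5, 1, 4, lower.tail = FALSE))

  same <- one_way_anova(list(c(2, 2), c(2, 2)))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)

  expect_error(one_way_anova(list(1, 2)), "residual degrees of freedom")
  expect_error(one_way_anova(list(c(1, 2))), "two groups")

  # F equals the squared pooled-variance t statistic for two groups
  set.seed(31)
  for (i in 1:5) {
    a <- rnorm(6); b <- rnorm(5, 1)
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(one_way_anova(list(a, b))$F, unname(tt$statistic)^2,
                 tolerance = 1e-10)
    expect_equal(one_way_anova(list(a, b))$p, tt$p.value, tolerance = 1e-10)
  }
})

test_that("intron bins cover the six categories and percentages close to 100", {
  feats <- data.frame(gene_id = sprintf("g%02d", 1:12),
                      n_exons = c(1, 1, 2, 3, 4, 5, 6, 7, 1, 2, 2, 8))
  labels <- setNames(rep(c("OG", "ASG"), each = 6), feats$gene_id)
  b <- bin_introns(feats, labels)
  expect_setequal(unique(b$bin), c("0", "1", "2", "3", "4", ">=5"))
  for (lv in c("OG", "ASG")) {
    expect_equal(sum(b$percent[b$label == lv]), 100, tolerance = 0.01)
  }
  # OG genes have 1,1,2,3,4,5 exons -> intron counts 0,0,1,2,3,4
  og <- b[b$label == "OG", ]
  expect_equal(og$count[og$bin == "0"], 2L)
  expect_equal(og$count[og$bin == ">=5"], 0L)
  # ASG genes have 6,7,1,2,2,8 exons -> intron counts 5,6,0,1,1,7
  asg <- b[b$label == "ASG", ]
  expect_equal(asg$count[asg$bin == ">=5"], 3L)

  # planted proportions are recovered exactly: 283/941 intron-less
  n <- 941L
  nex <- c(rep(1L, 283L), rep(2L, n - 283L))
  fx <- data.frame(gene_id = sprintf("o%04d", 1:n), n_exons = nex)
  bb <- bin_introns(fx, setNames(rep("OG", n), fx$gene_id))
  expect_equal(round(bb$percent[bb$bin == "0"], 2), 30.07)
})

test_that("chromosome distribution percentages and physical map are correct", {
  genes <- data.frame(gene_id = sprintf("g%02d", 1:60),
                      chromosome = c(rep("chr1", 50), rep("scafX", 10)),
                      strand = "+",
                      start = seq(1, by = 100, length.out = 60))
  genes$end <- genes$start + 50L
  exons <- data.frame(gene_id = genes$gene_id, start = genes$start,
                      end = genes$end)
  m <- gene_models(genes, exons, exons)
  labels <- setNames(c(rep("OG", 2), rep("ECG", 48), rep("OG", 10)),
                     genes$gene_id)
  cd <- chrom_distribution(labels, m, c(chr1 = 10000), class = "OG")
  expect_equal(cd$distribution$percent, 100 * 2 / 50)
  expect_equal(nrow(cd$unplaced), 10L)
  expect_equal(cd$physical_map$gene_id, c("g01", "g02"))
  expect_error(chrom_distribution(labels, m, c(chr1 = 10000), class = "OG",
                                  allow_unplaced = FALSE), "unknown chromosome")

  # all genes unplaced
  cd2 <- chrom_distribution(labels, m, c(chrZ = 5), class = "OG")
  expect_equal(cd2$distribution$n_all_genes, 0L)
  expect_equal(nrow(cd2$physical_map), 0L)
  expect_equal(nrow(cd2$unplaced), 12L)
})

test_that("spearman matches the closed form and the exact permutation null", {
  up <- spearman_test(1:6, c(10, 20, 30, 40, 50, 60))
  expect_equal(up$rho, 1)
  expect_equal(up$p, 0)

  r <- spearman_test(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(r$rho, 0.6)   # 1 - 6*4/(4*15)

  # tie-free data: rho equals 1 - 6*sum(d^2)/(n(n^2-1)) exactly
  set.seed(17)
  for (i in 1:10) {
    n <- sample(5:9, 1)
    x <- sample(100, n); y <- sample(100, n)
    d <- rank(x) - rank(y)
    expect_equal(spearman_test(x, y)$rho, 1 - 6 * sum(d^2) / (n * (n^2 - 1)))
    expect_equal(spearman_test(x, y)$rho,
                 unname(cor.test(x, y, method = "spearman")$estimate))
  }

  # exact permutation p agrees with cor.test's exact p for small n
  set.seed(23)
  for (i in 1:5) {
    n <- sample(5:7, 1)
    x <- sample(100, n); y <- sample(100, n)
    ex <- spearman_test(x, y, p_method = "exact")
    ref <- cor.test(x, y, method = "spearman", exact = TRUE)
    expect_equal(ex$p, ref$p.value, tolerance = 1e-10)
  }

  expect_warning(cs <- spearman_test(rep(1, 5), 1:5), "constant")
  expect_true(is.na(cs$rho))
})
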