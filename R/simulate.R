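# Planted-truth synthetic data: genomes with homolog structure across taxon
# scopes, the full-scale screen-count fixture, FPKM matrices with planted
# tissue/stage-specific genes, and Ct tables with planted fold changes.
# Every generator is deterministic given (config, seed): the R RNG state is
# set from the seed and restored on exit.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  force(code)
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_protein <- function(len) paste(sample(AA20, len, TRUE), collapse = "")

mutate_protein <- function(seq, p) {
  if (p <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- runif(length(chars)) < p
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(a)
      sample(setdiff(AA20, a), 1L), character(1))
  }
  paste(chars, collapse = "")
}

# non-stop codons, and a reverse codon table keyed by amino acid
codon_table <- function() {
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(codons)))
  split(codons[aa != "*"], aa[aa != "*"])
}

random_dna <- function(len, gc = 0.35) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), len, TRUE, prob = p), collapse = "")
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Configuration for the genome simulator
#'
#' Class-wise structural defaults echo the contrasts seen in real orphan-gene
#' surveys: species-specific genes are shorter and have fewer exons than
#' conserved genes.
#'
#' @param n_conserved,n_lineage,n_orphan Planted class sizes.
#' @param divergence Per-site substitution probability applied to planted
#'   homolog copies (i.i.d. substitutions, no indels).
#' @param n_chromosomes Number of focal chromosomes.
#' @param mean_protein_length Named vector of mean protein lengths (aa) per
#'   class.
#' @param mean_exons Named vector of mean exon counts per class.
#' @param intron_meanlog,intron_sdlog Log-normal intron length parameters
#'   (nt).
#' @param intergenic_range Min/max intergenic spacer length (nt).
#' @param gc_intron,gc_intergenic GC fraction targets of non-coding sequence.
#' @param n_decoys Unrelated decoy proteins added to every subject database.
#' @return A list of class `sim_genome_config`.
#' @export
sim_genome_config <- function(n_conserved = 60, n_lineage = 30, n_orphan = 30,
                              divergence = 0.05, n_chromosomes = 5,
                              mean_protein_length = c(CONSERVED = 370,
                                                      LINEAGE_SPECIFIC = 170,
                                                      SPECIES_SPECIFIC = 115),
                              mean_exons = c(CONSERVED = 5,
                                             LINEAGE_SPECIFIC = 2.4,
                                             SPECIES_SPECIFIC = 2.3),
                              intron_meanlog = log(200), intron_sdlog = 0.5,
                              intergenic_range = c(200, 800),
                              gc_intron = 0.25, gc_intergenic = 0.35,
                              n_decoys = 20) {
  stopifnot(divergence >= 0, divergence <= 1,
            n_conserved >= 0, n_lineage >= 0, n_orphan >= 0)
  structure(as.list(environment()), class = "sim_genome_config")
}

#' Simulate a focal genome with planted homology structure
#'
#' Generates focal gene models (CDS split into exons, introns and intergenic
#' spacers with their own GC targets, both strands) on `n_chromosomes`
#' chromosomes, with the class-wise length/exon biases of
#' [sim_genome_config()].  Planted `CONSERVED` genes get a mutated homolog in
#' the non-lineage subject database, planted `LINEAGE_SPECIFIC` genes only in
#' the lineage (non-focal) database, planted `SPECIES_SPECIFIC` genes
#' nowhere.  Subject ids carry the `NL|` / `LNF|` scope prefixes understood
#' by [default_scope_map()].
#'
#' @param config A [sim_genome_config].
#' @param seed Integer seed; identical seed + config reproduce identical
#'   output.
#' @return List of class `genome_simulation`: `genome` (chromosome
#'   [seq_records]), `proteins` (focal proteins), `models`
#'   ([gene_models]), `subjects` (named list of subject protein
#'   [seq_records]: `nonlineage_genomes`, `carrot_genome`), `truth`
#'   (data frame gene_id, label) and `config`.
#' @export
simulate_genomes <- function(config = sim_genome_config(), seed = 1) {
  stopifnot(inherits(config, "sim_genome_config"))
  with_seed(seed, {
    ct <- codon_table()
    classes <- rep(c("CONSERVED", "LINEAGE_SPECIFIC", "SPECIES_SPECIFIC"),
                   c(config$n_conserved, config$n_lineage, config$n_orphan))
    n <- length(classes)
    if (n == 0L) stop("no genes to simulate")
    ids <- sprintf("g%04d", seq_len(n))
    chrom_of <- sprintf("chr%02d", rep_len(seq_len(config$n_chromosomes), n))

    proteins <- character(n)
    gene_rows <- exon_rows <- cds_rows <- list()
    chrom_seq <- setNames(vector("list", config$n_chromosomes),
                          sprintf("chr%02d", seq_len(config$n_chromosomes)))
    chrom_seq[] <- list(character(0))
    offset <- setNames(integer(config$n_chromosomes), names(chrom_seq))

    for (i in seq_len(n)) {
      cls <- classes[i]
      plen <- max(50L, round(rlnorm(1, log(config$mean_protein_length[[cls]]) -
                                      0.35^2 / 2, 0.35)))
      proteins[i] <- random_protein(plen)
      aa <- strsplit(proteins[i], "")[[1]]
      cds <- paste0(paste(vapply(aa, function(a)
        sample(ct[[a]], 1L), character(1)), collapse = ""), "TAA")
      n_ex <- 1L + stats::rpois(1, max(config$mean_exons[[cls]] - 1, 0))
      n_ex <- min(n_ex, nchar(cds) %/% 10L)
      n_ex <- max(n_ex, 1L)
      # split the CDS into n_ex pieces of >= 3 nt
      if (n_ex > 1L) {
        cuts <- sort(sample(seq(3L, nchar(cds) - 3L, by = 3L), n_ex - 1L))
        piece_from <- c(1L, cuts + 1L)
        piece_to <- c(cuts, nchar(cds))
      } else {
        piece_from <- 1L; piece_to <- nchar(cds)
      }
      introns <- if (n_ex > 1L)
        pmax(30L, round(rlnorm(n_ex - 1L, config$intron_meanlog,
                               config$intron_sdlog))) else integer(0)
      # assemble the gene in transcript orientation
      parts <- character(0)
      rel_exons <- matrix(0L, n_ex, 2L)
      at <- 0L
      for (e in seq_len(n_ex)) {
        ex_seq <- substring(cds, piece_from[e], piece_to[e])
        rel_exons[e, ] <- c(at + 1L, at + nchar(ex_seq))
        parts <- c(parts, ex_seq)
        at <- at + nchar(ex_seq)
        if (e < n_ex) {
          parts <- c(parts, random_dna(introns[e], config$gc_intron))
          at <- at + introns[e]
        }
      }
      gene_seq <- paste(parts, collapse = "")
      strand <- sample(c("+", "-"), 1L)
      placed_seq <- if (strand == "+") gene_seq else revcomp(gene_seq)
      chr <- chrom_of[i]
      spacer <- random_dna(sample(config$intergenic_range[1]:
                                    config$intergenic_range[2], 1L),
                           config$gc_intergenic)
      start0 <- offset[[chr]] + nchar(spacer)
      chrom_seq[[chr]] <- c(chrom_seq[[chr]], spacer, placed_seq)
      offset[[chr]] <- start0 + nchar(gene_seq)
      # map transcript-relative exons to chromosome coordinates
      glen <- nchar(gene_seq)
      abs_exons <- if (strand == "+") {
        cbind(start0 + rel_exons[, 1L], start0 + rel_exons[, 2L])
      } else {
        cbind(start0 + glen + 1L - rel_exons[, 2L],
              start0 + glen + 1L - rel_exons[, 1L])
      }
      abs_exons <- abs_exons[order(abs_exons[, 1L]), , drop = FALSE]
      gene_rows[[i]] <- data.frame(
        gene_id = ids[i], chromosome = chr, strand = strand,
        start = start0 + 1L, end = start0 + glen,
        transcript_id = paste0(ids[i], ".t1"), stringsAsFactors = FALSE)
      exon_rows[[i]] <- data.frame(gene_id = ids[i],
                                   start = abs_exons[, 1L],
                                   end = abs_exons[, 2L],
                                   stringsAsFactors = FALSE)
      cds_rows[[i]] <- exon_rows[[i]]   # no UTRs in this model
    }

    genome <- seq_records(names(chrom_seq),
                          vapply(chrom_seq, paste, character(1), collapse = ""),
                          "nucleotide")
    models <- gene_models(do.call(rbind, gene_rows),
                          do.call(rbind, exon_rows),
                          do.call(rbind, cds_rows))
    focal <- seq_records(ids, proteins, "protein")

    make_db <- function(prefix, members) {
      hom_id <- paste0(prefix, "hom_", ids[members])
      hom_seq <- vapply(proteins[members], mutate_protein, character(1),
                        p = config$divergence)
      dec_id <- paste0(prefix, "decoy_", seq_len(config$n_decoys))
      dec_seq <- vapply(pmax(60L, round(rlnorm(config$n_decoys, log(250), 0.4))),
                        random_protein, character(1))
      seq_records(c(hom_id, dec_id), c(hom_seq, dec_seq), "protein")
    }
    subjects <- list(
      nonlineage_genomes = make_db("NL|phyto|", which(classes == "CONSERVED")),
      carrot_genome = make_db("LNF|carrot|", which(classes == "LINEAGE_SPECIFIC")))

    structure(list(genome = genome, proteins = focal, models = models,
                   subjects = subjects,
                   truth = data.frame(gene_id = ids, label = classes,
                                      stringsAsFactors = FALSE),
                   config = config, seed = seed),
              class = "genome_simulation")
  })
}

#' Generate cascade evidence from a genome simulation
#'
#' Runs the built-in [naive_search()] of the focal proteins against every
#' subject database of the simulation, returning hit tables keyed by the
#' matching stage names of [default_cascade_config()].
#'
#' @param sim A `genome_simulation`.
#' @param max_evalue Passed to [naive_search()].
#' @return Named list of [hit_table]s.
#' @export
evidence_from_simulation <- function(sim, max_evalue = 10) {
  stopifnot(inherits(sim, "genome_simulation"))
  list(
    nonlineage_genomes = naive_search(
      sim$proteins, sim$subjects$nonlineage_genomes, "prot_vs_prot",
      evidence_source("nonlineage_genomes", "non_lineage", "candidate",
                      "prot_vs_prot"), max_evalue = max_evalue),
    carrot_genome = naive_search(
      sim$proteins, sim$subjects$carrot_genome, "prot_vs_prot",
      evidence_source("carrot_genome", "lineage_non_focal", "candidate",
                      "prot_vs_prot"), max_evalue = max_evalue))
}

#' Published screen counts of the coriander orphan-gene survey
#'
#' The per-stage significant-hit counts of the 40,747-gene coriander screen:
#' five candidate stages (non-lineage genomes and transcripts, carrot genome,
#' carrot transcripts, celery genome) and four refinement screens with their
#' (lineage-to-conserved, species-to-conserved, species-to-lineage) flows.
#'
#' @return A list with `n_genes`, `candidate` (named hit counts, in stage
#'   order) and `refinement` (named list of length-3 flow vectors).
#' @export
coriander_stage_counts <- function() {
  list(n_genes = 40747L,
       candidate = c(nonlineage_genomes = 37975L, nonlineage_puts = 286L,
                     carrot_genome = 1102L, carrot_puts = 43L,
                     celery_genome = 227L),
       refinement = list(
         uniprot_kb = c(lineage_to_conserved = 18L, species_to_conserved = 8L,
                        species_to_lineage = 0L),
         nrdb = c(lineage_to_conserved = 135L, species_to_conserved = 18L,
                  species_to_lineage = 52L),
         ests = c(lineage_to_conserved = 20L, species_to_conserved = 13L,
                  species_to_lineage = 4L),
         nr_nt = c(lineage_to_conserved = 16L, species_to_conserved = 19L,
                   species_to_lineage = 59L)))
}

#' Deterministic full-scale count fixture
#'
#' Builds flag-style evidence tables over `n_genes` synthetic gene ids such
#' that every cascade stage sees exactly the configured number of hits among
#' its entrants, including the refinement stages' promotion flows.  Gene
#' selection is deterministic (lowest-id entrants first), so the fixture is
#' reproducible and runs at the 40,747-gene scale in seconds.
#'
#' @param stage_counts As returned by [coriander_stage_counts()] (the
#'   default).  Counts are validated: entrants may never go negative and
#'   flows may not exceed the genes available; violations raise an error
#'   naming the failing identity.
#' @return List with `genes`, `evidence` (named list of [hit_table]s keyed by
#'   stage name) and `config` (a [cascade_config] matching the stage names).
#' @export
simulate_count_fixture <- function(stage_counts = coriander_stage_counts()) {
  n <- stage_counts$n_genes
  genes <- sprintf("g%05d", seq_len(n))
  config <- default_cascade_config()
  cand <- config_stages(config, "candidate")
  refn <- config_stages(config, "refinement")
  cand_names <- vapply(cand, function(s) s$source$name, character(1))
  refn_names <- vapply(refn, function(s) s$source$name, character(1))
  if (!identical(sort(names(stage_counts$candidate)), sort(cand_names)) ||
      !identical(sort(names(stage_counts$refinement)), sort(refn_names))) {
    stop("stage_counts names must match the cascade stage names")
  }
  flag_hits <- function(gene_ids, subject_prefix, source_name) {
    if (!length(gene_ids)) return(hit_table(sources = source_name))
    hit_table(data.frame(
      query_id = gene_ids,
      subject_id = paste0(subject_prefix, source_name),
      source = source_name, pident = 95, length = 100L, mismatch = 5L,
      gapopen = 0L, qstart = 1L, qend = 100L, sstart = 1L, send = 100L,
      evalue = 1e-50, bitscore = 200, stringsAsFactors = FALSE),
      sources = source_name)
  }
  evidence <- list()
  pool <- genes
  label <- setNames(rep("SPECIES_SPECIFIC", n), genes)
  for (st in cand) {
    nm <- st$source$name
    k <- stage_counts$candidate[[nm]]
    if (k > length(pool)) {
      stop("inconsistent counts: stage '", nm, "' wants ", k,
           " hits but only ", length(pool), " genes enter it")
    }
    sel <- pool[seq_len(k)]
    prefix <- if (st$action == "assign_conserved") "NL|" else "LNF|"
    evidence[[nm]] <- flag_hits(sel, prefix, nm)
    label[sel] <- if (st$action == "assign_conserved") "CONSERVED"
                  else "LINEAGE_SPECIFIC"
    pool <- pool[-seq_len(k)]
  }
  for (nm in refn_names) {
    fl <- stage_counts$refinement[[nm]]
    lin <- names(label)[label == "LINEAGE_SPECIFIC"]
    spe <- names(label)[label == "SPECIES_SPECIFIC"]
    if (fl[["lineage_to_conserved"]] > length(lin)) {
      stop("inconsistent counts: stage '", nm, "' promotes ",
           fl[["lineage_to_conserved"]], " lineage genes but only ",
           length(lin), " remain")
    }
    if (fl[["species_to_conserved"]] + fl[["species_to_lineage"]] > length(spe)) {
      stop("inconsistent counts: stage '", nm, "' touches ",
           fl[["species_to_conserved"]] + fl[["species_to_lineage"]],
           " species-specific genes but only ", length(spe), " remain")
    }
    l2c <- lin[seq_len(fl[["lineage_to_conserved"]])]
    s2c <- spe[seq_len(fl[["species_to_conserved"]])]
    s2l <- setdiff(spe, s2c)[seq_len(fl[["species_to_lineage"]])]
    rows <- rbind(
      if (length(c(l2c, s2c)))
        as.data.frame(flag_hits(c(l2c, s2c), "NL|", nm)),
      if (length(s2l)) as.data.frame(flag_hits(s2l, "LNF|", nm)))
    evidence[[nm]] <- hit_table(rows, sources = nm)
    label[c(l2c, s2c)] <- "CONSERVED"
    label[s2l] <- "LINEAGE_SPECIFIC"
  }
  list(genes = genes, evidence = evidence, config = config)
}

#' Simulate an FPKM expression matrix with planted specificity
#'
#' Planted unique genes are positive (log-normal FPKM) in exactly one group's
#' samples and zero elsewhere; planted silent genes are all-zero; the rest
#' are expressed in two or more groups.
#'
#' @param gene_ids Character vector of gene ids.
#' @param groups Character vector of group names (2-6).
#' @param n_unique Named integer vector of planted unique-gene counts per
#'   group.
#' @param n_silent Number of planted all-zero genes.
#' @param n_replicates Samples per group.
#' @param seed Integer seed.
#' @param fpkm_meanlog,fpkm_sdlog Log-normal FPKM parameters for expressed
#'   values.
#' @param forced_unique Optional named character vector `gene_id -> group`
#'   forcing specific genes to be the planted uniques of a group (counted
#'   against `n_unique`); used to plant cross-design intersections.
#' @return List: `matrix` (an `expression_matrix`), `truth` (gene_id, type,
#'   group).
#' @export
simulate_expression <- function(gene_ids, groups, n_unique, n_silent = 0,
                                n_replicates = 3, seed = 1,
                                fpkm_meanlog = log(10), fpkm_sdlog = 1,
                                forced_unique = NULL) {
  stopifnot(length(groups) >= 2, all(names(n_unique) %in% groups))
  n_unique <- n_unique[groups]
  n_unique[is.na(n_unique)] <- 0L
  names(n_unique) <- groups
  if (sum(n_unique) + n_silent > length(gene_ids)) {
    stop("planted counts exceed the number of genes")
  }
  with_seed(seed, {
    assign_group <- setNames(rep(NA_character_, length(gene_ids)), gene_ids)
    if (!is.null(forced_unique)) {
      stopifnot(all(names(forced_unique) %in% gene_ids),
                all(forced_unique %in% groups))
      assign_group[names(forced_unique)] <- forced_unique
    }
    for (g in groups) {
      have <- sum(assign_group == g, na.rm = TRUE)
      need <- n_unique[[g]] - have
      if (need < 0) stop("forced_unique exceeds n_unique for group ", g)
      free <- names(assign_group)[is.na(assign_group)]
      assign_group[sample(free, need)] <- g
    }
    free <- names(assign_group)[is.na(assign_group)]
    silent <- sample(free, n_silent)
    shared <- setdiff(free, silent)
    samples <- as.vector(outer(groups, seq_len(n_replicates),
                               function(g, r) paste0(g, "_r", r)))
    design <- setNames(rep(groups, n_replicates), samples)
    m <- matrix(0, length(gene_ids), length(samples),
                dimnames = list(gene_ids, samples))
    rl <- function(k) rlnorm(k, fpkm_meanlog, fpkm_sdlog)
    for (gid in names(assign_group)[!is.na(assign_group)]) {
      cols <- samples[design == assign_group[[gid]]]
      m[gid, cols] <- rl(length(cols))
    }
    ks <- 2:length(groups)
    for (gid in shared) {
      on <- sample(groups, ks[sample.int(length(ks), 1L)])
      cols <- samples[design %in% on]
      m[gid, cols] <- rl(length(cols))
    }
    truth <- data.frame(
      gene_id = gene_ids,
      type = ifelse(gene_ids %in% silent, "silent",
                    ifelse(!is.na(assign_group[gene_ids]), "unique", "shared")),
      group = unname(assign_group[gene_ids]),
      stringsAsFactors = FALSE)
    list(matrix = expression_matrix(m, design), truth = truth)
  })
}

#' Simulate a qPCR Ct table with planted fold changes
#'
#' Reference-gene Ct values are drawn as `baseline + noise`; target Ct values
#' as `ct_reference + dct_base - log2(fold) + noise`, so at zero noise
#' [delta_delta_ct()] recovers the planted folds exactly.
#'
#' @param folds Named list per gene of named numeric vectors `group -> fold`;
#'   the calibrator group's fold must be 1 and all folds positive.
#' @param calibrator Calibrator group name.
#' @param n_replicates Biological replicates per group (default 3).
#' @param noise_sd Ct noise standard deviation (cycles).
#' @param baseline_ct Reference-gene baseline Ct.
#' @param dct_base Baseline dCt of each target gene under calibrator
#'   conditions (recycled across genes).
#' @param seed Integer seed.
#' @return List: `table` (a [qpcr_table]), `truth` (gene, group,
#'   planted_fold).
#' @export
simulate_qpcr <- function(folds, calibrator, n_replicates = 3,
                          noise_sd = 0.15, baseline_ct = 20, dct_base = 6,
                          seed = 1) {
  stopifnot(is.list(folds), length(folds) > 0)
  dct_base <- rep_len(dct_base, length(folds))
  with_seed(seed, {
    rows <- list()
    truth <- list()
    for (i in seq_along(folds)) {
      gene <- names(folds)[i]
      fv <- folds[[i]]
      if (any(fv <= 0)) stop("planted folds must be positive")
      if (!calibrator %in% names(fv) || fv[[calibrator]] != 1) {
        stop("gene ", gene, ": calibrator group fold must be present and 1")
      }
      for (g in names(fv)) {
        ref <- baseline_ct + rnorm(n_replicates, 0, noise_sd)
        tgt <- ref + dct_base[i] - log2(fv[[g]]) +
          rnorm(n_replicates, 0, noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = gene, group = g, replicate = seq_len(n_replicates),
          ct_target = tgt, ct_reference = ref, stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- data.frame(
          gene = gene, group = g, planted_fold = fv[[g]],
          stringsAsFactors = FALSE)
      }
    }
    list(table = qpcr_table(do.call(rbind, rows), calibrator),
         truth = do.call(rbind, truth))
  })
}

#' Write a genome simulation to disk in standard formats
#'
#' Emits `genome.fasta`, `proteins.fasta`, `annotation.gff3`, one protein
#' FASTA per subject database, and `truth.tsv`.
#'
#' @param sim A `genome_simulation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "genome_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(sim$genome, file.path(dir, "genome.fasta"))
  write_fasta(sim$proteins, file.path(dir, "proteins.fasta"))
  write_gff(sim$models, file.path(dir, "annotation.gff3"))
  for (nm in names(sim$subjects)) {
    write_fasta(sim$subjects[[nm]], file.path(dir, paste0(nm, ".fasta")))
  }
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
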