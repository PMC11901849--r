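simple_hits <- function(gene_ids, source_name, prefix = "NL|",
                        evalue = 1e-20) {
  if (!length(gene_ids)) return(hit_table(sources = source_name))
  hit_table(data.frame(
    query_id = gene_ids, subject_id = paste0(prefix, "s", seq_along(gene_ids)),
    source = source_name, pident = 90, length = 50L, mismatch = 5L,
    gapopen = 0L, qstart = 1L, qend = 50L, sstart = 1L, send = 50L,
    evalue = evalue, bitscore = 100, stringsAsFactors = FALSE),
    sources = source_name)
}

test_that("genes without hits become species-specific by default", {
  res <- classify(c("a", "b", "c"), list())
  expect_equal(res$labels$label, rep("SPECIES_SPECIFIC", 3))
  expect_equal(res$labels$decided_at_stage, rep("final_default", 3))
})

test_that("a hit at a lineage candidate stage yields a lineage label", {
  ev <- list(carrot_genome = simple_hits("a", "carrot_genome", "LNF|"))
  res <- classify(c("a", "b"), ev)
  expect_equal(res$labels$label[res$labels$gene_id == "a"], "LINEAGE_SPECIFIC")
  expect_equal(res$labels$decided_at_stage[res$labels$gene_id == "a"],
               "carrot_genome")
  expect_equal(res$labels$label[res$labels$gene_id == "b"], "SPECIES_SPECIFIC")
})

test_that("every gene hit at stage 1 is conserved", {
  genes <- sprintf("g%02d", 1:10)
  ev <- list(nonlineage_genomes = simple_hits(genes, "nonlineage_genomes"))
  res <- classify(genes, ev)
  expect_equal(unique(res$labels$label), "CONSERVED")
})

test_that("refinement promotes species-specific genes on lineage-scoped hits", {
  ev <- list(nrdb = simple_hits("a", "nrdb", "LNF|"))
  res <- classify(c("a", "b"), ev)
  expect_equal(res$labels$label[res$labels$gene_id == "a"], "LINEAGE_SPECIFIC")
  expect_equal(res$labels$decided_at_stage[res$labels$gene_id == "a"], "nrdb")
  # no refinement hits -> label unchanged
  expect_equal(res$labels$label[res$labels$gene_id == "b"], "SPECIES_SPECIFIC")
})

test_that("focal-scoped refinement hits are ignored", {
  ev <- list(nrdb = simple_hits("a", "nrdb", "FOC|"))
  res <- classify(c("a"), ev)
  expect_equal(res$labels$label, "SPECIES_SPECIFIC")
})

test_that("evidence naming unknown genes or unresolvable scopes errors", {
  ev <- list(nonlineage_genomes = simple_hits("ghost", "nonlineage_genomes"))
  expect_error(classify(c("a", "b"), ev), "ghost")
  ev2 <- list(nrdb = simple_hits("a", "nrdb", "???|"))
  expect_error(classify(c("a"), ev2), "scope")
})

test_that("the full-scale count fixture reproduces every printed screen count", {
  fx <- simulate_count_fixture()
  res <- classify(fx$genes, fx$evidence, fx$config)
  tl <- res$tallies
  cand <- tl[tl$phase == "candidate", ]
  expect_equal(cand$n_entering, c(40747L, 2772L, 2486L, 1384L, 1341L))
  expect_equal(cand$n_hit, c(37975L, 286L, 1102L, 43L, 227L))
  expect_equal(cand$n_remaining, c(2772L, 2486L, 1384L, 1341L, 1114L))
  refn <- tl[tl$phase == "refinement", ]
  expect_equal(refn$n_entering_lineage, c(1372L, 1354L, 1271L, 1255L))
  expect_equal(refn$n_entering_species, c(1114L, 1106L, 1036L, 1019L))
  expect_equal(class_totals(res),
               c(CONSERVED = 38508L, LINEAGE_SPECIFIC = 1298L,
                 SPECIES_SPECIFIC = 941L))
})

test_that("class counts are conserved and labels only broaden", {
  set.seed(101)
  for (rep in 1:10) {
    inst <- random_cascade_instance(15)
    res <- classify(inst$genes, inst$evidence, inst$config)
    expect_equal(sum(class_totals(res)), length(inst$genes))
    # monotone broadening along each gene's history
    rank_of <- c(SPECIES_SPECIFIC = 1, LINEAGE_SPECIFIC = 2, CONSERVED = 3)
    for (g in unique(res$history$gene_id)) {
      h <- res$history[res$history$gene_id == g, ]
      ranks <- rank_of[h$label]
      expect_true(all(diff(ranks) >= 0) || nrow(h) == 1L)
    }
  }
})

test_that("adding evidence never increases the species-specific count", {
  set.seed(202)
  for (rep in 1:5) {
    inst <- random_cascade_instance(15)
    res_full <- classify(inst$genes, inst$evidence, inst$config)
    for (drop in seq_along(inst$evidence)) {
      res_less <- classify(inst$genes, inst$evidence[-drop], inst$config)
      expect_gte(class_totals(res_less)[["SPECIES_SPECIFIC"]],
                 class_totals(res_full)[["SPECIES_SPECIFIC"]])
    }
  }
})

test_that("the cascade computes the same labels as the brute-force scope rule", {
  set.seed(303)
  for (rep in 1:25) {
    inst <- random_cascade_instance(sample(5:25, 1))
    res <- classify(inst$genes, inst$evidence, inst$config)
    expect_equal(res$labels$label[match(inst$genes, res$labels$gene_id)],
                 oracle_scope_rule(inst$genes, inst$evidence, inst$config))
  }
})

test_that("tally_report carries stage rows, conservation identity and totals", {
  fx <- simulate_count_fixture()
  res <- classify(fx$genes, fx$evidence, fx$config)
  rep <- tally_report(res)
  cand <- rep[rep$phase == "candidate", ]
  expect_equal(cand$n_entering[-1L], cand$n_remaining[-nrow(cand)])
  expect_true(all(cand$n_entering ==
                    cand$n_assigned_conserved + cand$n_assigned_lineage +
                    cand$n_remaining))
  fin <- rep[rep$stage == "final_total", ]
  expect_equal(c(fin$n_assigned_conserved, fin$n_assigned_lineage,
                 fin$n_remaining), c(38508L, 1298L, 941L))

  # empty input: header-only stage table plus the final summary row
  res0 <- classify(character(0), list(), fx$config)
  rep0 <- tally_report(res0)
  expect_true(all(rep0$n_entering[rep0$phase != "summary"] == 0L))

  f <- tempfile(fileext = ".tsv")
  tally_report(res, f)
  expect_true(file.exists(f))
  back <- read.delim(f)
  expect_equal(nrow(back), nrow(rep))
})

test_that("cascade configs validate stage ordering and phases", {
  s1 <- stage_spec(1, evidence_source("a", "non_lineage", "candidate"),
                   "assign_conserved")
  s2 <- stage_spec(2, evidence_source("b", "non_lineage", "refinement"),
                   "refine_scoped")
  expect_error(cascade_config(list(s2, s1)), "strictly increase")
  expect_error(stage_spec(1, evidence_source("a", "non_lineage", "candidate"),
                          "refine_scoped"), "candidate-phase")
  expect_error(stage_spec(1, evidence_source("a", "non_lineage", "refinement"),
                          "assign_conserved"), "refinement-phase")
  cfg <- cascade_config(list(s1, s2), scope_map = default_scope_map())
  expect_s3_class(cfg, "cascade_config")
})
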