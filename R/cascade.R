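# The two-phase taxon-scoped classification cascade.
#
# Candidate phase: genes are screened stage by stage; a significant hit at a
# non-lineage stage labels the gene CONSERVED and removes it from all later
# stages; a hit at a lineage stage labels it LINEAGE_SPECIFIC (candidate) and
# removes it likewise; survivors become SPECIES_SPECIFIC candidates.
#
# Refinement phase: still-candidate genes (everything not already CONSERVED)
# are screened against broad databases whose subjects are taxonomically
# scoped; a non-lineage-scoped hit promotes to CONSERVED, a
# lineage-but-not-focal hit promotes SPECIES_SPECIFIC to LINEAGE_SPECIFIC
# (the gene stays in later refinement stages), focal hits are ignored.
# Labels only ever broaden.

CLASS_LEVELS <- c("CONSERVED", "LINEAGE_SPECIFIC", "SPECIES_SPECIFIC")

#' Declare one cascade stage
#'
#' @param order_index Positive integer giving the stage's position; candidate
#'   stages must precede refinement stages.
#' @param source An [evidence_source].
#' @param action `"assign_conserved"` or `"assign_lineage"` for candidate
#'   stages, `"refine_scoped"` for refinement stages.
#' @return A list of class `stage_spec`.
#' @export
stage_spec <- function(order_index, source,
                       action = c("assign_conserved", "assign_lineage",
                                  "refine_scoped")) {
  action <- match.arg(action)
  stopifnot(inherits(source, "evidence_source"),
            is.numeric(order_index), order_index >= 1)
  if (source$phase == "candidate" && action == "refine_scoped") {
    stop("candidate-phase stages must use assign_conserved or assign_lineage")
  }
  if (source$phase == "refinement" && action != "refine_scoped") {
    stop("refinement-phase stages must use refine_scoped")
  }
  structure(list(order_index = as.integer(order_index), source = source,
                 action = action),
            class = "stage_spec")
}

#' Assemble a cascade configuration
#'
#' @param stages List of [stage_spec] objects with strictly increasing
#'   `order_index`; all candidate stages must precede all refinement stages.
#' @param evalue_threshold Significance cut-off applied to all evidence
#'   (strictly-less-than rule); default `1e-3`.
#' @param scope_map Named character vector mapping subject-id regular
#'   expressions to scopes in `non_lineage`, `lineage_non_focal`, `focal`;
#'   used to adjudicate refinement hits. Patterns are tried in order.
#' @return A list of class `cascade_config`.
#' @export
cascade_config <- function(stages, evalue_threshold = 1e-3, scope_map = NULL) {
  stopifnot(length(stages) >= 1, evalue_threshold > 0)
  idx <- vapply(stages, function(s) s$order_index, integer(1))
  if (any(diff(idx) <= 0)) stop("stage order_index values must strictly increase")
  phases <- vapply(stages, function(s) s$source$phase, character(1))
  if (any(phases == "refinement") &&
      max(which(phases == "candidate")) > min(which(phases == "refinement")))
    stop("candidate stages must precede refinement stages")
  nm <- vapply(stages, function(s) s$source$name, character(1))
  if (anyDuplicated(nm)) stop("stage source names must be unique")
  if (!is.null(scope_map)) {
    if (!all(scope_map %in% c("non_lineage", "lineage_non_focal", "focal")))
      stop("scope_map values must be valid scopes")
  }
  structure(list(stages = stages, evalue_threshold = evalue_threshold,
                 scope_map = scope_map),
            class = "cascade_config")
}

#' Default cascade topology for a focal Apiaceae genome
#'
#' Five candidate stages (non-lineage complete genomes by BLASTP-like search,
#' non-lineage assembled transcripts by TBLASTN-like search, then the two
#' sequenced lineage relatives: carrot genome, carrot transcripts, celery
#' genome) followed by four refinement screens (UniProt-KB, the non-redundant
#' protein database, public ESTs, and the Nr/Nt nucleotide collection), each
#' adjudicated through the subject scope map.
#'
#' @param scope_map As in [cascade_config()]; the default maps subject-id
#'   prefixes `NL|`, `LNF|` and `FOC|` (the simulators' convention) to the
#'   three scopes.
#' @param evalue_threshold Significance cut-off, default `1e-3`.
#' @return A [cascade_config].
#' @export
default_cascade_config <- function(scope_map = default_scope_map(),
                                   evalue_threshold = 1e-3) {
  st <- list(
    stage_spec(1, evidence_source("nonlineage_genomes", "non_lineage",
                                  "candidate", "prot_vs_prot"), "assign_conserved"),
    stage_spec(2, evidence_source("nonlineage_puts", "non_lineage",
                                  "candidate", "prot_vs_nucl"), "assign_conserved"),
    stage_spec(3, evidence_source("carrot_genome", "lineage_non_focal",
                                  "candidate", "prot_vs_prot"), "assign_lineage"),
    stage_spec(4, evidence_source("carrot_puts", "lineage_non_focal",
                                  "candidate", "prot_vs_nucl"), "assign_lineage"),
    stage_spec(5, evidence_source("celery_genome", "lineage_non_focal",
                                  "candidate", "prot_vs_prot"), "assign_lineage"),
    stage_spec(6, evidence_source("uniprot_kb", "non_lineage",
                                  "refinement", "prot_vs_prot"), "refine_scoped"),
    stage_spec(7, evidence_source("nrdb", "non_lineage",
                                  "refinement", "prot_vs_prot"), "refine_scoped"),
    stage_spec(8, evidence_source("ests", "non_lineage",
                                  "refinement", "prot_vs_nucl"), "refine_scoped"),
    stage_spec(9, evidence_source("nr_nt", "non_lineage",
                                  "refinement", "nucl_vs_nucl"), "refine_scoped"))
  cascade_config(st, evalue_threshold = evalue_threshold, scope_map = scope_map)
}

#' @rdname default_cascade_config
#' @export
default_scope_map <- function() {
  c("^NL\\|" = "non_lineage", "^LNF\\|" = "lineage_non_focal",
    "^FOC\\|" = "focal")
}

resolve_scope <- function(subject_ids, scope_map, stage_name) {
  scopes <- rep(NA_character_, length(subject_ids))
  for (pat in names(scope_map)) {
    hit <- is.na(scopes) & grepl(pat, subject_ids)
    scopes[hit] <- scope_map[[pat]]
  }
  if (anyNA(scopes)) {
    stop("cannot resolve taxon scope of subject(s) ",
         paste(unique(subject_ids[is.na(scopes)]), collapse = ", "),
         " at stage '", stage_name, "'")
  }
  scopes
}

config_stages <- function(config, phase) {
  Filter(function(s) s$source$phase == phase, config$stages)
}

# best hit per query: minimum E-value, ties by bitscore desc then subject asc
best_hits <- function(table) {
  df <- as.data.frame(table)
  if (!nrow(df)) return(df)
  o <- order(df$query_id, df$evalue, -df$bitscore, df$subject_id)
  df <- df[o, , drop = FALSE]
  df[!duplicated(df$query_id), , drop = FALSE]
}

check_known_genes <- function(table, genes, stage_name) {
  unknown <- setdiff(unique(table$query_id), genes)
  if (length(unknown)) {
    stop("evidence at stage '", stage_name, "' references gene id(s) absent ",
         "from the gene list: ", paste(head(unknown, 5), collapse = ", "),
         if (length(unknown) > 5) ", ...")
  }
}

new_tally <- function(stage, phase, n_entering = 0L, n_hit = 0L,
                      n_assigned_conserved = 0L, n_assigned_lineage = 0L,
                      n_upgraded_to_lineage = 0L, n_remaining = 0L,
                      n_entering_lineage = NA_integer_,
                      n_entering_species = NA_integer_) {
  data.frame(stage = stage, phase = phase, n_entering = n_entering,
             n_entering_lineage = n_entering_lineage,
             n_entering_species = n_entering_species,
             n_hit = n_hit, n_assigned_conserved = n_assigned_conserved,
             n_assigned_lineage = n_assigned_lineage,
             n_upgraded_to_lineage = n_upgraded_to_lineage,
             n_remaining = n_remaining, stringsAsFactors = FALSE)
}

empty_tally <- function() {
  new_tally(stage = character(0), phase = character(0),
            n_entering = integer(0), n_hit = integer(0),
            n_assigned_conserved = integer(0), n_assigned_lineage = integer(0),
            n_upgraded_to_lineage = integer(0), n_remaining = integer(0),
            n_entering_lineage = integer(0), n_entering_species = integer(0))
}

#' Run the candidate phase of the cascade
#'
#' Genes are screened through the candidate stages in configured order.  A
#' gene with at least one significant hit at an `assign_conserved` stage is
#' labelled `CONSERVED` and leaves the cascade; a hit at an `assign_lineage`
#' stage labels it `LINEAGE_SPECIFIC` (candidate) and removes it likewise;
#' survivors of all candidate stages become `SPECIES_SPECIFIC` candidates
#' (`decided_at_stage` `"final_default"`).
#'
#' @param genes Character vector of all focal gene ids.
#' @param evidence Named list of [hit_table]s, one per candidate stage name;
#'   evidence must already be significance-filtered (see
#'   [filter_significant()]).  Stages without an entry see no hits.
#' @param config A [cascade_config].
#' @return A list with `labels` (data frame: gene_id, label,
#'   decided_at_stage, best_subject, best_evalue), `tallies` (one row per
#'   stage) and `history` (gene_id, stage, label records of every
#'   assignment).
#' @export
run_candidate_phase <- function(genes, evidence, config) {
  stopifnot(inherits(config, "cascade_config"))
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("duplicate gene ids in gene list")
  stages <- config_stages(config, "candidate")
  lab <- data.frame(gene_id = genes,
                    label = rep(NA_character_, length(genes)),
                    decided_at_stage = rep(NA_character_, length(genes)),
                    best_subject = rep(NA_character_, length(genes)),
                    best_evalue = rep(NA_real_, length(genes)),
                    stringsAsFactors = FALSE)
  remaining <- genes
  tallies <- list()
  history <- list()
  for (st in stages) {
    nm <- st$source$name
    tab <- evidence[[nm]]
    hit_genes <- character(0)
    best <- NULL
    if (!is.null(tab)) {
      stopifnot(inherits(tab, "hit_table"))
      check_known_genes(tab, genes, nm)
      best <- best_hits(tab)
      hit_genes <- intersect(remaining, best$query_id)
    }
    n_in <- length(remaining)
    n_hit <- length(hit_genes)
    label <- if (st$action == "assign_conserved") "CONSERVED" else "LINEAGE_SPECIFIC"
    if (n_hit) {
      i <- match(hit_genes, lab$gene_id)
      lab$label[i] <- label
      lab$decided_at_stage[i] <- nm
      j <- match(hit_genes, best$query_id)
      lab$best_subject[i] <- best$subject_id[j]
      lab$best_evalue[i] <- best$evalue[j]
      history[[length(history) + 1L]] <-
        data.frame(gene_id = hit_genes, stage = nm, label = label,
                   stringsAsFactors = FALSE)
      remaining <- setdiff(remaining, hit_genes)
    }
    tallies[[length(tallies) + 1L]] <- new_tally(
      nm, "candidate", n_entering = n_in, n_hit = n_hit,
      n_assigned_conserved = if (label == "CONSERVED") n_hit else 0L,
      n_assigned_lineage = if (label == "LINEAGE_SPECIFIC") n_hit else 0L,
      n_remaining = n_in - n_hit)
  }
  if (length(remaining)) {
    i <- match(remaining, lab$gene_id)
    lab$label[i] <- "SPECIES_SPECIFIC"
    lab$decided_at_stage[i] <- "final_default"
    history[[length(history) + 1L]] <-
      data.frame(gene_id = remaining, stage = "final_default",
                 label = "SPECIES_SPECIFIC", stringsAsFactors = FALSE)
  }
  list(labels = lab,
       tallies = if (length(tallies)) do.call(rbind, tallies) else empty_tally(),
       history = if (length(history)) do.call(rbind, history) else
         data.frame(gene_id = character(), stage = character(),
                    label = character(), stringsAsFactors = FALSE))
}

#' Run the refinement phase of the cascade
#'
#' Candidate `LINEAGE_SPECIFIC` and `SPECIES_SPECIFIC` genes are screened
#' against broad databases stage by stage.  Hit subjects are resolved to a
#' taxon scope through `config$scope_map`: a `non_lineage` hit promotes the
#' gene to `CONSERVED` (it leaves the cascade); a `lineage_non_focal` hit
#' promotes `SPECIES_SPECIFIC` to `LINEAGE_SPECIFIC` (the gene stays in later
#' stages); `focal` hits are ignored.  When a gene has both kinds of hit at
#' one stage the broader promotion wins.  Labels never narrow.
#'
#' @param interim Result of [run_candidate_phase()].
#' @param evidence Named list of significance-filtered [hit_table]s, one per
#'   refinement stage name.
#' @param config A [cascade_config] with a `scope_map`.
#' @return A `classification_result`: list with `labels`, `tallies`
#'   (candidate + refinement stage rows) and `history`.
#' @export
run_refinement_phase <- function(interim, evidence, config) {
  stopifnot(inherits(config, "cascade_config"))
  stages <- config_stages(config, "refinement")
  lab <- interim$labels
  history <- list(interim$history)
  tallies <- list(interim$tallies)
  if (length(stages) && is.null(config$scope_map)) {
    stop("refinement stages require a scope_map in the cascade config")
  }
  for (st in stages) {
    nm <- st$source$name
    active <- lab$gene_id[lab$label != "CONSERVED"]
    lab_in <- lab$label[lab$label != "CONSERVED"]
    tab <- evidence[[nm]]
    n_in <- length(active)
    promoted_cons <- character(0)
    promoted_lin <- character(0)
    n_hit <- 0L
    if (!is.null(tab) && nrow(tab)) {
      stopifnot(inherits(tab, "hit_table"))
      check_known_genes(tab, lab$gene_id, nm)
      df <- as.data.frame(tab)
      df <- df[df$query_id %in% active, , drop = FALSE]
      if (nrow(df)) {
        df$scope <- resolve_scope(df$subject_id, config$scope_map, nm)
        df <- df[df$scope != "focal", , drop = FALSE]
      }
      if (nrow(df)) {
        n_hit <- length(unique(df$query_id))
        cons_hits <- df[df$scope == "non_lineage", , drop = FALSE]
        promoted_cons <- unique(cons_hits$query_id)
        lin_hits <- df[df$scope == "lineage_non_focal", , drop = FALSE]
        cur <- lab$label[match(unique(lin_hits$query_id), lab$gene_id)]
        promoted_lin <- setdiff(
          unique(lin_hits$query_id)[cur == "SPECIES_SPECIFIC"], promoted_cons)
        if (length(promoted_cons)) {
          best <- best_hits(hit_table(cons_hits, sources = hit_sources(tab)))
          i <- match(promoted_cons, lab$gene_id)
          lab$label[i] <- "CONSERVED"
          lab$decided_at_stage[i] <- nm
          j <- match(promoted_cons, best$query_id)
          lab$best_subject[i] <- best$subject_id[j]
          lab$best_evalue[i] <- best$evalue[j]
          history[[length(history) + 1L]] <-
            data.frame(gene_id = promoted_cons, stage = nm,
                       label = "CONSERVED", stringsAsFactors = FALSE)
        }
        if (length(promoted_lin)) {
          best <- best_hits(hit_table(lin_hits, sources = hit_sources(tab)))
          i <- match(promoted_lin, lab$gene_id)
          lab$label[i] <- "LINEAGE_SPECIFIC"
          lab$decided_at_stage[i] <- nm
          j <- match(promoted_lin, best$query_id)
          lab$best_subject[i] <- best$subject_id[j]
          lab$best_evalue[i] <- best$evalue[j]
          history[[length(history) + 1L]] <-
            data.frame(gene_id = promoted_lin, stage = nm,
                       label = "LINEAGE_SPECIFIC", stringsAsFactors = FALSE)
        }
      }
    }
    tallies[[length(tallies) + 1L]] <- new_tally(
      nm, "refinement", n_entering = n_in, n_hit = n_hit,
      n_assigned_conserved = length(promoted_cons),
      n_upgraded_to_lineage = length(promoted_lin),
      n_remaining = n_in - length(promoted_cons),
      n_entering_lineage = sum(lab_in == "LINEAGE_SPECIFIC"),
      n_entering_species = sum(lab_in == "SPECIES_SPECIFIC"))
  }
  structure(list(labels = lab,
                 tallies = do.call(rbind, tallies),
                 history = do.call(rbind, history)),
            class = "classification_result")
}

#' Classify all focal genes through the full cascade
#'
#' Composes [run_candidate_phase()] and [run_refinement_phase()].  Evidence
#' tables are significance-filtered at `config$evalue_threshold` first (the
#' filter is idempotent, so pre-filtered evidence is fine).
#'
#' @param genes Character vector of focal gene ids.
#' @param evidence Named list of [hit_table]s keyed by stage source name.
#' @param config A [cascade_config]; default [default_cascade_config()].
#' @return A `classification_result` (see [run_refinement_phase()]); its
#'   `labels` element has one row per input gene.
#' @export
classify <- function(genes, evidence = list(), config = default_cascade_config()) {
  stopifnot(inherits(config, "cascade_config"))
  evidence <- lapply(evidence, filter_significant,
                     threshold = config$evalue_threshold)
  interim <- run_candidate_phase(genes, evidence, config)
  run_refinement_phase(interim, evidence, config)
}

#' @export
print.classification_result <- function(x, ...) {
  tot <- table(factor(x$labels$label, levels = CLASS_LEVELS))
  cat("Cascade classification of", nrow(x$labels), "genes\n")
  for (lv in CLASS_LEVELS) cat(sprintf("  %-17s %d\n", lv, tot[[lv]]))
  invisible(x)
}

#' Per-class totals of a classification result
#' @param result A `classification_result`.
#' @return Named integer vector over `CONSERVED`, `LINEAGE_SPECIFIC`,
#'   `SPECIES_SPECIFIC`.
#' @export
class_totals <- function(result) {
  stopifnot(inherits(result, "classification_result"))
  tab <- table(factor(result$labels$label, levels = CLASS_LEVELS))
  setNames(as.integer(tab), CLASS_LEVELS)
}

#' Stage-count report
#'
#' One row per cascade stage with the tally fields, plus a `final_total` row
#' carrying the per-class totals.
#'
#' @param result A `classification_result`.
#' @param path Optional path; when given the table is written as TSV.
#' @return The report data frame, invisibly when written to `path`.
#' @export
tally_report <- function(result, path = NULL) {
  stopifnot(inherits(result, "classification_result"))
  rep <- result$tallies
  tot <- class_totals(result)
  final <- new_tally("final_total", "summary",
                     n_assigned_conserved = tot[["CONSERVED"]],
                     n_assigned_lineage = tot[["LINEAGE_SPECIFIC"]],
                     n_remaining = tot[["SPECIES_SPECIFIC"]])
  final$n_entering <- nrow(result$labels)
  rep <- rbind(rep, final)
  rownames(rep) <- NULL
  if (!is.null(path)) {
    write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(rep))
  }
  rep
}

#' Write the per-gene classification table
#'
#' @param result A `classification_result`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_classification <- function(result, path) {
  stopifnot(inherits(result, "classification_result"))
  write.table(result$labels, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
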