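#' Pool gene-level alteration events from all pipeline stages
#'
#' Builds the event table over which prioritization and cohort frequency
#' operate: one event per focal CNV call (direction gain/loss), one per
#' high/low expression call (intermediate and not-expressed states are not
#' alterations), one per passed variant, and — only when
#' `config$count_fusions_in_integration` is set — one per fusion partner.
#'
#' @param cnv_calls Output of [call_gene_cnv()].
#' @param expr_calls Output of [classify_expression()].
#' @param passed_variants The `passed` table of [run_variant_stage()].
#' @param fusions Filtered fusions from [filter_fusions()] (optional).
#' @param config A [pipeline_config()].
#' @return An alteration-event data.frame (columns `gene_id`, `sample_id`,
#'   `alteration_type`, `direction`, `evidence`).
#' @export
collect_events <- function(cnv_calls, expr_calls, passed_variants,
                           fusions = NULL, config = pipeline_config()) {
  ev <- list(empty_events())
  if (nrow(cnv_calls) > 0) {
    ev <- c(ev, list(data.frame(
      gene_id = cnv_calls$gene_id, sample_id = cnv_calls$sample_id,
      alteration_type = "cnv",
      direction = ifelse(cnv_calls$status == "amplified", "gain", "loss"),
      evidence = paste0("cnv:", cnv_calls$segment_key),
      stringsAsFactors = FALSE)))
  }
  altered <- expr_calls[expr_calls$status %in% c("high", "low"), , drop = FALSE]
  if (nrow(altered) > 0) {
    ev <- c(ev, list(data.frame(
      gene_id = altered$gene_id, sample_id = altered$sample_id,
      alteration_type = "expression",
      direction = ifelse(altered$status == "high", "gain", "loss"),
      evidence = sprintf("expr:pct=%.1f", altered$percentile),
      stringsAsFactors = FALSE)))
  }
  if (nrow(passed_variants) > 0) {
    ev <- c(ev, list(data.frame(
      gene_id = passed_variants$gene_id, sample_id = passed_variants$sample_id,
      alteration_type = "mutation", direction = "not_applicable",
      evidence = paste0("mut:", passed_variants$chrom, ":",
                        passed_variants$pos, ":", passed_variants$ref, ">",
                        passed_variants$alt),
      stringsAsFactors = FALSE)))
  }
  if (!is.null(fusions) && config$count_fusions_in_integration) {
    ev <- c(ev, list(fusions_to_events(fusions)))
  }
  do.call(rbind, ev)
}

#' Step 1: genes with concordant focal copy number and expression
#'
#' Selects genes where, in at least one sample, a focal amplification
#' coincides with high expression or a focal deletion with low expression —
#' the per-sample dosage reading of "positive correlation of copy number and
#' expression". Cross-sample combinations enter only at step 3.
#'
#' @param cnv_calls Output of [call_gene_cnv()].
#' @param expr_calls Output of [classify_expression()].
#' @return Character vector of selected gene ids.
#' @export
step1_cnv_expression <- function(cnv_calls, expr_calls) {
  if (nrow(cnv_calls) == 0) return(character(0))
  ekey <- paste(expr_calls$gene_id, expr_calls$sample_id)
  status <- expr_calls$status[match(paste(cnv_calls$gene_id,
                                          cnv_calls$sample_id), ekey)]
  concordant <- (cnv_calls$status == "amplified" & status %in% "high") |
    (cnv_calls$status == "deleted" & status %in% "low")
  sort(unique(cnv_calls$gene_id[concordant]))
}

#' Step 2: mutated genes with detectable transcript or altered copy number
#'
#' Selects genes carrying at least one passed variant that either sits in a
#' sample where the gene's transcript is detectable, or belongs to a gene
#' with a focal copy-number call in any sample.
#'
#' @param passed_variants The `passed` table of [run_variant_stage()].
#' @param expr_calls Output of [classify_expression()].
#' @param cnv_calls Output of [call_gene_cnv()].
#' @return Character vector of selected gene ids.
#' @export
step2_mutation_support <- function(passed_variants, expr_calls, cnv_calls) {
  if (nrow(passed_variants) == 0) return(character(0))
  expressed <- detectable(passed_variants$gene_id, passed_variants$sample_id,
                          expr_calls)
  has_cnv <- passed_variants$gene_id %in% cnv_calls$gene_id
  sort(unique(passed_variants$gene_id[expressed | has_cnv]))
}

#' Step 3: prioritize genes altered by multiple mechanisms
#'
#' The candidate universe is the union of the step-1 and step-2 gene lists.
#' For each candidate, events are pooled across *all* samples and the number
#' of distinct alteration types counted; a gene is prioritized when it
#' reaches `min_alteration_types` (default 2) within or across samples.
#' Detectability is evidence, never a type: only cnv, expression-change and
#' mutation (and fusion, if enabled) events count.
#'
#' @param step1,step2 Gene-id vectors from [step1_cnv_expression()] and
#'   [step2_mutation_support()].
#' @param all_events Event table from [collect_events()].
#' @param config A [pipeline_config()].
#' @return A data.frame of gene alteration profiles, one row per candidate
#'   gene, sorted by descending `n_types`, descending `n_samples`, gene id:
#'   columns `gene_id`, `n_types`, `types_present`, `n_samples`,
#'   `samples_affected`, `prioritized`.
#' @export
step3_prioritize <- function(step1, step2, all_events,
                             config = pipeline_config()) {
  candidates <- sort(union(step1, step2))
  ev <- all_events[all_events$gene_id %in% candidates, , drop = FALSE]
  profiles <- lapply(candidates, function(g) {
    ge <- ev[ev$gene_id == g, , drop = FALSE]
    types <- sort(unique(ge$alteration_type))
    samples <- sort(unique(ge$sample_id))
    data.frame(gene_id = g, n_types = length(types),
               types_present = paste(types, collapse = ","),
               n_samples = length(samples),
               samples_affected = paste(samples, collapse = ","),
               prioritized = length(types) >= config$min_alteration_types,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(profiles, list(data.frame(
    gene_id = character(0), n_types = integer(0), types_present = character(0),
    n_samples = integer(0), samples_affected = character(0),
    prioritized = logical(0), stringsAsFactors = FALSE))))
  out[order(-out$n_types, -out$n_samples, out$gene_id), , drop = FALSE]
}

#' Run the full integration pipeline on a cohort
#'
#' Convenience driver over the whole method: gene-level CNV calling,
#' expression classification, variant filtering with cross-validation,
#' fusion filtering, event pooling and the three-step prioritization.
#'
#' @param genes,segments,expression,exome,transcriptome,fusions The cohort
#'   tables, as read by the `read_*` functions or produced by
#'   [simulate_cohort()].
#' @param config A [pipeline_config()].
#' @return A list with components `cnv_calls`, `expr_calls`, `variant_set`,
#'   `fusions_kept`, `events`, `step1`, `step2`, `profiles`, and
#'   `prioritized` (the prioritized gene ids).
#' @export
run_pipeline <- function(genes, segments, expression, exome, transcriptome,
                         fusions = NULL, config = pipeline_config()) {
  cnv_calls <- call_gene_cnv(segments, genes, config)
  expr_calls <- classify_expression(expression, config)
  variant_set <- run_variant_stage(exome, transcriptome, config)
  fusions_kept <- if (is.null(fusions)) NULL else
    filter_fusions(fusions, config)
  events <- collect_events(cnv_calls, expr_calls, variant_set$passed,
                           fusions_kept, config)
  step1 <- step1_cnv_expression(cnv_calls, expr_calls)
  step2 <- step2_mutation_support(variant_set$passed, expr_calls, cnv_calls)
  profiles <- step3_prioritize(step1, step2, events, config)
  list(cnv_calls = cnv_calls, expr_calls = expr_calls,
       variant_set = variant_set, fusions_kept = fusions_kept,
       events = events, step1 = step1, step2 = step2, profiles = profiles,
       prioritized = profiles$gene_id[profiles$prioritized])
}
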