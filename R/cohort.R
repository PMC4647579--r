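#' Per-gene cumulative alteration frequency across a cohort
#'
#' For each gene, the per-type frequency is the fraction of cohort samples
#' carrying at least one event of that type, and the cumulative frequency is
#' the fraction of samples carrying at least one event of *any* type — a
#' sample-set union, never a sum, so a sample altered by three mechanisms
#' counts once. The union bound
#' `max(per-type) <= cumulative <= min(1, sum(per-type))` holds by
#' construction.
#'
#' @param events An alteration-event data.frame (columns `gene_id`,
#'   `sample_id`, `alteration_type`; e.g. from [collect_events()] or an
#'   external cohort export read as TSV).
#' @param sample_ids Character vector of all cohort samples (the denominator;
#'   samples without events count).
#' @param gene_ids Character vector of genes to report (defaults to the genes
#'   present in `events`).
#' @return A data.frame with one row per gene: `gene_id`, `n_samples`,
#'   `freq_mutation`, `freq_cnv`, `freq_expression`, `freq_fusion`,
#'   `freq_cnv_expression` (union of the non-mutation types) and
#'   `freq_cumulative`.
#' @export
cumulative_frequency <- function(events, sample_ids,
                                 gene_ids = sort(unique(events$gene_id))) {
  n <- length(sample_ids)
  if (n == 0) stop("sample_ids is empty: cohort size must be positive",
                   call. = FALSE)
  if (nrow(events) > 0) {
    unknown <- setdiff(unique(events$sample_id), sample_ids)
    if (length(unknown) > 0) {
      stop("events reference sample(s) not in sample_ids: ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    }
  }
  frac <- function(ge, types) {
    length(unique(ge$sample_id[ge$alteration_type %in% types])) / n
  }
  rows <- lapply(gene_ids, function(g) {
    ge <- events[events$gene_id == g, , drop = FALSE]
    data.frame(
      gene_id = g, n_samples = n,
      freq_mutation = frac(ge, "mutation"),
      freq_cnv = frac(ge, "cnv"),
      freq_expression = frac(ge, "expression"),
      freq_fusion = frac(ge, "fusion"),
      freq_cnv_expression = frac(ge, c("cnv", "expression", "fusion")),
      freq_cumulative = length(unique(ge$sample_id)) / n,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, list(data.frame(
    gene_id = character(0), n_samples = integer(0), freq_mutation = numeric(0),
    freq_cnv = numeric(0), freq_expression = numeric(0),
    freq_fusion = numeric(0), freq_cnv_expression = numeric(0),
    freq_cumulative = numeric(0), stringsAsFactors = FALSE))))
}

#' Select genes by cohort mutation frequency
#'
#' Keeps genes mutated in at least `cohort_min_mutation_freq` of samples
#' (default 3%, inclusive), sorted by descending cumulative frequency.
#'
#' @param records Output of [cumulative_frequency()].
#' @param config A [pipeline_config()].
#' @return Character vector of gene ids.
#' @export
select_frequent_genes <- function(records, config = pipeline_config()) {
  kept <- records[records$freq_mutation >= config$cohort_min_mutation_freq, ,
                  drop = FALSE]
  kept$gene_id[order(-kept$freq_cumulative, kept$gene_id)]
}

#' Three-class gene typology from alteration frequencies
#'
#' Operationalizes the qualitative split between genes altered primarily by
#' mutation, genes altered preferentially by copy number / expression, and
#' mixed genes: with `other` the union-based frequency of non-mutation
#' events, a gene is `mutation_dominant` when
#' `freq_mutation >= ratio * other`, `cnv_expression_dominant` when
#' `other >= ratio * freq_mutation` (ratio default 3), otherwise `mixed`;
#' a gene with no events of either kind is `mixed`. Raw frequencies are
#' reported alongside so users can re-classify under another ratio.
#'
#' @param records Output of [cumulative_frequency()].
#' @param config A [pipeline_config()].
#' @return `records` with an added `gene_class` column.
#' @export
classify_gene <- function(records, config = pipeline_config()) {
  r <- config$class_dominance_ratio
  fm <- records$freq_mutation
  other <- records$freq_cnv_expression
  cls <- rep("mixed", nrow(records))
  nonzero <- fm > 0 | other > 0
  cls[nonzero & fm >= r * other] <- "mutation_dominant"
  cls[nonzero & other >= r * fm] <- "cnv_expression_dominant"
  records$gene_class <- cls
  records
}

#' Export an oncoprint-style alteration matrix as text
#'
#' Genes as rows, samples as columns; each cell concatenates the ordered
#' single-letter codes of the alteration types hitting that gene in that
#' sample (`A` amplification, `D` deletion, `H` high expression, `L` low
#' expression, `M` mutation, `F` fusion), or `"."` for none.
#'
#' @param events An alteration-event data.frame.
#' @param sample_ids Cohort sample ids (column order).
#' @param gene_ids Genes to include (row order; defaults to all in `events`).
#' @return A character matrix with gene rownames and sample colnames.
#' @export
oncoprint_matrix <- function(events, sample_ids,
                             gene_ids = sort(unique(events$gene_id))) {
  code <- function(type, dir) {
    switch(type,
           cnv = if (identical(dir, "loss")) "D" else "A",
           expression = if (identical(dir, "loss")) "L" else "H",
           mutation = "M", fusion = "F", "?")
  }
  m <- matrix(".", nrow = length(gene_ids), ncol = length(sample_ids),
              dimnames = list(gene_ids, sample_ids))
  if (nrow(events) == 0) return(m)
  ev <- events[events$gene_id %in% gene_ids &
                 events$sample_id %in% sample_ids, , drop = FALSE]
  if (nrow(ev) == 0) return(m)
  codes <- mapply(code, ev$alteration_type,
                  if ("direction" %in% names(ev)) ev$direction else
                    rep(NA_character_, nrow(ev)))
  key <- paste(ev$gene_id, ev$sample_id)
  for (k in unique(key)) {
    parts <- sort(unique(codes[key == k]))
    gs <- strsplit(k, " ", fixed = TRUE)[[1]]
    m[gs[1], gs[2]] <- paste(parts, collapse = "")
  }
  m
}
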