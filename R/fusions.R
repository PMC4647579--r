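#' Filter fusion candidates by read-pair support
#'
#' Keeps candidates supported by at least `min_fusion_read_pairs` read pairs
#' (default 10; the minimum is inclusive, so 10 passes and 9 drops).
#'
#' @param fusions A fusion data.frame from [read_fusions()].
#' @param config A [pipeline_config()].
#' @return The surviving fusion data.frame.
#' @export
filter_fusions <- function(fusions, config = pipeline_config()) {
  fusions[fusions$read_pairs >= config$min_fusion_read_pairs, , drop = FALSE]
}

#' Convert fusions to gene-level alteration events
#'
#' Each fusion contributes one event per partner gene (5' and 3'), direction
#' `not_applicable`; a read-through (both partners the same gene) contributes
#' a single event. Events carry the fusion pair as provenance.
#'
#' @param fusions Filtered fusions from [filter_fusions()].
#' @return An alteration-event data.frame (columns `gene_id`, `sample_id`,
#'   `alteration_type`, `direction`, `evidence`).
#' @export
fusions_to_events <- function(fusions) {
  if (nrow(fusions) == 0) return(empty_events())
  ev <- paste0("fusion:", fusions$gene5, "-", fusions$gene3,
               ":", fusions$sample_id)
  events <- rbind(
    data.frame(gene_id = fusions$gene5, sample_id = fusions$sample_id,
               alteration_type = "fusion", direction = "not_applicable",
               evidence = ev, stringsAsFactors = FALSE),
    data.frame(gene_id = fusions$gene3, sample_id = fusions$sample_id,
               alteration_type = "fusion", direction = "not_applicable",
               evidence = ev, stringsAsFactors = FALSE)
  )
  unique(events)  # read-throughs collapse to one event
}

empty_events <- function() {
  data.frame(gene_id = character(0), sample_id = character(0),
             alteration_type = character(0), direction = character(0),
             evidence = character(0), stringsAsFactors = FALSE)
}
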