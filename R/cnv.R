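#' Classify copy-number segments as focal or arm-level
#'
#' Segments shorter than `focal_max_length` (default 10 Mb) are focal and
#' enter gene-level calling; segments of 10 Mb or longer are arm-level and
#' treated as non-specific chromosome-scale events, excluded downstream. A
#' segment of exactly the threshold length is arm-level: the focal filter is
#' the strict "less than" actually applied downstream.
#'
#' @param segments A segment data.frame from [read_segments()].
#' @param config A [pipeline_config()].
#' @return The input with an added `scale` column (`"focal"`/`"arm_level"`).
#' @export
classify_segments <- function(segments, config = pipeline_config()) {
  len <- segments$end - segments$start
  segments$scale <- ifelse(len < config$focal_max_length, "focal", "arm_level")
  segments
}

segment_status <- function(copy_number, config) {
  ifelse(copy_number >= config$amp_min_copies, "amplified",
         ifelse(copy_number <= config$del_max_copies, "deleted", "neutral"))
}

#' Gene-level copy-number calls from focal segments
#'
#' Annotates genes onto focal, non-neutral segments and emits one call per
#' (gene, sample) pair. A gene is assigned to a segment by any overlap of at
#' least one base (configurable minimum overlap fraction, default 0). Genes
#' overlapping only arm-level or only copy-neutral segments yield no call.
#' When a gene overlaps several qualifying focal segments in one sample, the
#' segment with the most extreme copy number (largest
#' `|copy_number - neutral_copies|`) wins; ties break toward amplification,
#' then toward the leftmost segment. Mixed amplified/deleted overlaps are
#' resolved by the same rule and flagged in the provenance key.
#'
#' @param segments A segment data.frame from [read_segments()].
#' @param genes A gene-model data.frame from [read_gene_models()].
#' @param config A [pipeline_config()].
#' @return A data.frame with columns `gene_id`, `sample_id`, `status`
#'   (`amplified`/`deleted`), `focal` (always `TRUE`), `copy_number`,
#'   `segment_key`.
#' @export
call_gene_cnv <- function(segments, genes, config = pipeline_config()) {
  empty <- data.frame(gene_id = character(0), sample_id = character(0),
                      status = character(0), focal = logical(0),
                      copy_number = numeric(0), segment_key = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(segments) == 0 || nrow(genes) == 0) return(empty)

  seg <- classify_segments(segments, config)
  seg$status <- segment_status(seg$copy_number, config)
  seg <- seg[seg$scale == "focal" & seg$status != "neutral", , drop = FALSE]
  if (nrow(seg) == 0) return(empty)

  hits <- GenomicRanges::findOverlaps(df_to_granges(genes), df_to_granges(seg))
  gi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  if (config$min_overlap_fraction > 0 && length(gi) > 0) {
    ov <- pmin(genes$end[gi], seg$end[si]) - pmax(genes$start[gi], seg$start[si])
    keep <- ov / (genes$end[gi] - genes$start[gi]) >= config$min_overlap_fraction
    gi <- gi[keep]; si <- si[keep]
  }
  if (length(gi) == 0) return(empty)

  cand <- data.frame(
    gene_id = genes$gene_id[gi],
    sample_id = seg$sample_id[si],
    status = seg$status[si],
    copy_number = seg$copy_number[si],
    seg_start = seg$start[si],
    seg_key = sprintf("%s:%s:%.0f-%.0f", seg$sample_id[si], seg$chrom[si],
                      seg$start[si], seg$end[si]),
    stringsAsFactors = FALSE
  )
  cand$extremity <- abs(cand$copy_number - config$neutral_copies)

  # most extreme copy number wins; ties to amplification, then leftmost
  ord <- order(cand$gene_id, cand$sample_id, -cand$extremity,
               cand$status != "amplified", cand$seg_start)
  cand <- cand[ord, , drop = FALSE]
  grp <- paste(cand$gene_id, cand$sample_id)
  first <- !duplicated(grp)
  mixed <- tapply(cand$status, grp, function(s) length(unique(s)) > 1)
  win <- cand[first, , drop = FALSE]
  win$segment_key <- ifelse(mixed[paste(win$gene_id, win$sample_id)],
                            paste0(win$seg_key, ";mixed_overlap"), win$seg_key)
  data.frame(gene_id = win$gene_id, sample_id = win$sample_id,
             status = win$status, focal = TRUE,
             copy_number = win$copy_number, segment_key = win$segment_key,
             stringsAsFactors = FALSE)
}
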