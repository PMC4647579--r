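#' Variant filtering
#'
#' The variant stage applies, in a fixed documented order, the somatic
#' filters: effect-class screen (synonymous and unannotated-effect calls
#' drop), hard coverage filter, germline-catalog subtraction,
#' functional-prediction voting, exome/transcriptome cross-validation, and
#' removal of calls with no assignable gene. Each operation returns a
#' *filtered variant set*: a list with `passed` and `rejected` data.frames
#' where every rejected record carries the first failing reason, and
#' `nrow(passed) + nrow(rejected) == nrow(input)` always holds.
#'
#' @name variant-filters
NULL

filtered_set <- function(passed, rejected, reason = NULL) {
  if (!is.null(reason) && nrow(rejected) > 0) rejected$reason <- reason
  if (nrow(rejected) > 0 && !"reason" %in% names(rejected)) {
    stop("internal: rejected records lack a reason")
  }
  if (nrow(rejected) == 0) rejected$reason <- character(0)
  structure(list(passed = passed, rejected = rejected),
            class = "filtered_variants")
}

#' @export
print.filtered_variants <- function(x, ...) {
  cat("filtered variant set:", nrow(x$passed), "passed,",
      nrow(x$rejected), "rejected\n")
  if (nrow(x$rejected) > 0) print(table(x$rejected$reason))
  invisible(x)
}

#' Hard coverage filter
#'
#' Variants below `min_coverage` reads (default 5) are removed to reduce
#' false positives; "below" is strict, so coverage of exactly 5 passes.
#'
#' @param variants A variant data.frame from [read_variants()].
#' @param config A [pipeline_config()].
#' @return A filtered variant set (see [variant-filters]).
#' @export
filter_coverage <- function(variants, config = pipeline_config()) {
  ok <- variants$coverage >= config$min_coverage
  filtered_set(variants[ok, , drop = FALSE],
               variants[!ok, , drop = FALSE], "low_coverage")
}

#' Germline-catalog subtraction
#'
#' A variant present in the germline polymorphism catalog (dbSNP) but absent
#' from the somatic catalog (COSMIC) is treated as a known germline variant
#' and subtracted; COSMIC membership rescues a dbSNP-listed variant.
#'
#' @inheritParams filter_coverage
#' @return A filtered variant set.
#' @export
subtract_germline <- function(variants) {
  germline <- variants$in_dbsnp & !variants$in_cosmic
  filtered_set(variants[!germline, , drop = FALSE],
               variants[germline, , drop = FALSE], "dbsnp_only")
}

#' Functional-prediction consensus vote
#'
#' A variant is kept when at least `min_deleterious_votes` of its
#' `n_predictors` prediction slots (default 2 of 3) call it deleterious; a
#' missing verdict counts as not-deleterious. Truncating effects (nonsense,
#' frameshift, splice) bypass the vote and are always kept: substitution
#' scorers do not score them, and they are the variants least safe to drop
#' silently.
#'
#' @inheritParams filter_coverage
#' @return Logical vector, one element per variant.
#' @export
vote_deleterious <- function(variants, config = pipeline_config()) {
  votes <- (variants$pred1 == "D") + (variants$pred2 == "D") +
    (variants$pred3 == "D")
  variants$effect %in% c("nonsense", "frameshift", "splice") |
    votes >= config$min_deleterious_votes
}

filter_deleterious <- function(variants, config = pipeline_config()) {
  ok <- vote_deleterious(variants, config)
  filtered_set(variants[ok, , drop = FALSE],
               variants[!ok, , drop = FALSE], "not_deleterious")
}

variant_key <- function(v, with_alleles = TRUE) {
  if (with_alleles) paste(v$sample_id, v$chrom, v$pos, v$ref, v$alt)
  else paste(v$sample_id, v$chrom, v$pos)
}

#' Cross-validate exome variants against transcriptome variants
#'
#' An exome variant is considered a true genomic variant only when the same
#' (sample, chrom, pos, ref, alt) call was independently observed in
#' transcriptome sequencing. The passing record is the exome record (exome
#' coverage retained). With `config$cross_validate_alleles = FALSE` the match
#' is on position only.
#'
#' @param exome,transcriptome Variant data.frames from [read_variants()].
#' @param config A [pipeline_config()].
#' @return A filtered variant set over the exome records.
#' @export
cross_validate <- function(exome, transcriptome, config = pipeline_config()) {
  ok <- variant_key(exome, config$cross_validate_alleles) %in%
    variant_key(transcriptome, config$cross_validate_alleles)
  filtered_set(exome[ok, , drop = FALSE],
               exome[!ok, , drop = FALSE], "no_transcriptome_support")
}

#' Run the full variant-filtering stage
#'
#' Applies, in order: drop synonymous/other effect classes, coverage filter,
#' germline subtraction, prediction vote, transcriptome cross-validation,
#' drop calls with empty `gene_id` (unassignable to a gene, kept in the
#' rejected output). Only the reason labels depend on this order — the
#' passed set does not, as the predicates are independent.
#'
#' @param exome,transcriptome Variant data.frames from [read_variants()].
#' @param config A [pipeline_config()].
#' @return A filtered variant set; `passed` holds the exome records that
#'   survived every filter.
#' @export
run_variant_stage <- function(exome, transcriptome,
                              config = pipeline_config()) {
  nonsyn <- !exome$effect %in% c("synonymous", "other")
  stage0 <- filtered_set(exome[nonsyn, , drop = FALSE],
                         exome[!nonsyn, , drop = FALSE], "synonymous")
  stage1 <- filter_coverage(stage0$passed, config)
  stage2 <- subtract_germline(stage1$passed)
  stage3 <- filter_deleterious(stage2$passed, config)
  stage4 <- cross_validate(stage3$passed, transcriptome, config)
  unassigned <- is.na(stage4$passed$gene_id) | stage4$passed$gene_id == ""
  stage5 <- filtered_set(stage4$passed[!unassigned, , drop = FALSE],
                         stage4$passed[unassigned, , drop = FALSE],
                         "unassigned_gene")
  rejected <- rbind(stage0$rejected, stage1$rejected, stage2$rejected,
                    stage3$rejected, stage4$rejected, stage5$rejected)
  filtered_set(stage5$passed, rejected)
}
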