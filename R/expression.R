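#' Classify expression per gene and sample by percentile rank
#'
#' Genes with `log10(FPKM + 1)` below the noise floor (default 0.1) are
#' `not_expressed` and excluded from percentile computation. Among the
#' remaining (expressed) genes of each sample, the empirical percentile rank
#' is `100 * (rank - 1) / (n - 1)` with ties sharing the mean percentile of
#' their rank span; a sample with a single expressed gene gets percentile 50.
#' Status is `high` when the percentile is strictly above `high_percentile`
#' (default 60), `low` when strictly below `low_percentile` (default 40),
#' `intermediate` otherwise. Ranks only: the classification is invariant
#' under any strictly monotone transform of the expression values, and an
#' all-ties sample classifies everything `intermediate`.
#'
#' @param expr A long expression data.frame from [read_expression_matrix()]
#'   (columns `gene_id`, `sample_id`, `fpkm`, `log_expr`).
#' @param config A [pipeline_config()].
#' @return A data.frame with columns `gene_id`, `sample_id`, `fpkm`,
#'   `log_expr`, `percentile` (`NA` for not-expressed genes), `status`.
#' @export
classify_expression <- function(expr, config = pipeline_config()) {
  stopifnot(all(c("gene_id", "sample_id", "fpkm", "log_expr") %in% names(expr)))
  out <- expr[c("gene_id", "sample_id", "fpkm", "log_expr")]
  out$percentile <- NA_real_
  out$status <- "not_expressed"
  for (s in unique(out$sample_id)) {
    in_sample <- out$sample_id == s
    expressed <- in_sample & out$log_expr >= config$expr_noise_floor
    n <- sum(expressed)
    if (n == 0) {
      stop("sample ", s, " has no expressed genes above the noise floor",
           call. = FALSE)
    }
    pct <- if (n == 1) 50 else
      100 * (rank(out$log_expr[expressed], ties.method = "average") - 1) / (n - 1)
    out$percentile[expressed] <- pct
    out$status[expressed] <- ifelse(pct > config$high_percentile, "high",
                                    ifelse(pct < config$low_percentile, "low",
                                           "intermediate"))
  }
  out
}

#' Is a gene's transcript detectable in a sample?
#'
#' Detectability is evidence that a mutation is expressed, not an alteration
#' in itself: a transcript is detectable iff its expression status in that
#' sample is anything other than `not_expressed`. A (gene, sample) pair
#' absent from the expression calls is undetectable.
#'
#' @param gene_id,sample_id Vectors of gene and sample identifiers (recycled
#'   to common length).
#' @param expr_calls Output of [classify_expression()].
#' @return Logical vector.
#' @export
detectable <- function(gene_id, sample_id, expr_calls) {
  key <- paste(gene_id, sample_id)
  det <- expr_calls$status != "not_expressed"
  ekey <- paste(expr_calls$gene_id, expr_calls$sample_id)
  key %in% ekey[det]
}
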