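#' Genomic interval conventions
#'
#' All coordinates inside the pipeline are 0-based, half-open `[start, end)`:
#' BED input is taken as-is; GTF (1-based inclusive) and VCF (1-based
#' positions) are converted at ingest. Chromosome names are normalized once at
#' ingest by stripping any leading `"chr"`, so `"chr3"` and `"3"` refer to the
#' same sequence throughout.
#'
#' @name interval-conventions
NULL

#' Normalize chromosome names
#'
#' Strips a leading `"chr"` (case-insensitive) so both UCSC-style and
#' Ensembl-style names map to one internal scheme.
#'
#' @param chrom Character vector of chromosome names.
#' @return Character vector of normalized names.
#' @export
normalize_chrom <- function(chrom) {
  sub("^[Cc][Hh][Rr]", "", as.character(chrom))
}

check_intervals <- function(chrom, start, end, what = "interval") {
  bad <- which(!(end > start))
  if (length(bad) > 0) {
    stop(what, " with end <= start at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Test overlap of genomic intervals
#'
#' Two half-open intervals overlap iff they share a chromosome and at least
#' one base: `a.start < b.end && b.start < a.end`. Abutting intervals
#' (`[10,20)` vs `[20,30)`) do not overlap; mismatched chromosomes return
#' `FALSE`, never an error. Vectorized with the usual recycling.
#'
#' @param chrom_a,start_a,end_a First interval(s).
#' @param chrom_b,start_b,end_b Second interval(s).
#' @return Logical vector.
#' @export
#' @examples
#' interval_overlaps("1", 10, 20, "1", 19, 30)  # TRUE, one shared base
#' interval_overlaps("1", 10, 20, "1", 20, 30)  # FALSE, half-open abutting
interval_overlaps <- function(chrom_a, start_a, end_a,
                              chrom_b, start_b, end_b) {
  check_intervals(chrom_a, start_a, end_a, "interval a")
  check_intervals(chrom_b, start_b, end_b, "interval b")
  normalize_chrom(chrom_a) == normalize_chrom(chrom_b) &
    start_a < end_b & start_b < end_a
}

# data.frame(chrom, start, end, ...) -> GRanges in the internal convention
# (shifted to 1-based closed for IRanges arithmetic; lengths are preserved).
df_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = normalize_chrom(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}
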