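#' Read gene models
#'
#' Ingests the gene universe from BED (0-based half-open, name in column 4,
#' optional score and strand columns), GTF (1-based inclusive `gene`
#' features, converted at the boundary), or the package's own TSV dialect as
#' produced by [write_table()]. Duplicate symbols are legal (a warning is
#' logged, symbols are never merged); duplicate `gene_id`s are an error.
#'
#' @param path Input file path.
#' @param format `"bed"`, `"gtf"` or `"tsv"`.
#' @return A data.frame with columns `gene_id`, `symbol`, `chrom`, `start`,
#'   `end`, `strand` (internal 0-based half-open coordinates, normalized
#'   chromosome names).
#' @export
read_gene_models <- function(path, format = c("bed", "gtf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("gene model file not found: ", path, call. = FALSE)
  genes <- switch(format,
    bed = {
      df <- utils::read.table(path, sep = "\t", header = FALSE,
                              comment.char = "#", stringsAsFactors = FALSE)
      if (ncol(df) < 4) stop("BED gene file needs >= 4 columns (name in col 4)",
                             call. = FALSE)
      data.frame(
        gene_id = as.character(df[[4]]),
        symbol = as.character(df[[4]]),
        chrom = normalize_chrom(df[[1]]),
        start = as.integer(df[[2]]),
        end = as.integer(df[[3]]),
        strand = if (ncol(df) >= 6) as.character(df[[6]]) else "unknown",
        stringsAsFactors = FALSE
      )
    },
    gtf = {
      if (!requireNamespace("rtracklayer", quietly = TRUE)) {
        stop("reading GTF requires the rtracklayer package", call. = FALSE)
      }
      gr <- rtracklayer::import(path, format = "gtf")
      gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
      if (length(gr) == 0) stop("no gene features in GTF: ", path, call. = FALSE)
      md <- S4Vectors::mcols(gr)
      sym <- if ("gene_name" %in% names(md)) as.character(md$gene_name) else
        as.character(md$gene_id)
      data.frame(
        gene_id = as.character(md$gene_id),
        symbol = sym,
        chrom = normalize_chrom(GenomicRanges::seqnames(gr)),
        start = GenomicRanges::start(gr) - 1L,  # 1-based inclusive -> 0-based half-open
        end = GenomicRanges::end(gr),
        strand = as.character(GenomicRanges::strand(gr)),
        stringsAsFactors = FALSE
      )
    },
    tsv = {
      df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
      req <- c("gene_id", "symbol", "chrom", "start", "end", "strand")
      missing_cols <- setdiff(req, names(df))
      if (length(missing_cols) > 0) {
        stop("gene TSV lacks column(s): ", paste(missing_cols, collapse = ", "),
             call. = FALSE)
      }
      df$chrom <- normalize_chrom(df$chrom)
      df[req]
    }
  )
  genes$strand[!genes$strand %in% c("+", "-")] <- "unknown"
  if (nrow(genes) == 0) stop("zero genes read from ", path, call. = FALSE)
  check_intervals(genes$chrom, genes$start, genes$end, "gene")
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicated gene_id(s): ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)])[1:3],
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(genes$symbol)) {
    warning("duplicate gene symbol(s) kept as distinct models: ",
            paste(unique(genes$symbol[duplicated(genes$symbol)])[1:3],
                  collapse = ", "), call. = FALSE)
  }
  genes
}

#' Read copy-number segments
#'
#' SEG-style TSV with columns `sample_id`, `chrom`, `start`, `end`,
#' `copy_number` and optional `n_probes`. Coordinates are taken as 0-based
#' half-open. Overlapping segments within one sample are kept but flagged
#' with a warning (downstream gene calling resolves them deterministically).
#'
#' @param path Input file path.
#' @return A data.frame of validated segments.
#' @export
read_segments <- function(path) {
  if (!file.exists(path)) stop("segment file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("sample_id", "chrom", "start", "end", "copy_number")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop("segment file lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"n_probes" %in% names(df)) df$n_probes <- NA_integer_
  df$chrom <- normalize_chrom(df$chrom)
  check_intervals(df$chrom, df$start, df$end, "segment")
  if (any(df$copy_number < 0)) {
    stop("negative copy number at row(s) ",
         paste(utils::head(which(df$copy_number < 0), 5), collapse = ", "),
         call. = FALSE)
  }
  warn_self_overlaps(df)
  df[c(req, "n_probes")]
}

warn_self_overlaps <- function(segments) {
  for (s in unique(segments$sample_id)) {
    seg <- segments[segments$sample_id == s, , drop = FALSE]
    hits <- GenomicRanges::findOverlaps(df_to_granges(seg),
                                        drop.self = TRUE, drop.redundant = TRUE)
    if (length(hits) > 0) {
      warning("sample ", s, " has ", length(hits),
              " self-overlapping segment pair(s); kept as-is", call. = FALSE)
    }
  }
  invisible(segments)
}

#' Read a gene-by-sample FPKM matrix
#'
#' Wide TSV (first column `gene_id`, one column per sample) or the long
#' per-record dialect written by [write_table()] (columns `gene_id`,
#' `sample_id`, `fpkm`). The log-transformed expression
#' `log_expr = log10(fpkm + 1)` is derived at ingest.
#'
#' @param path Input file path.
#' @return A long data.frame with columns `gene_id`, `sample_id`, `fpkm`,
#'   `log_expr`, one row per matrix cell.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (all(c("gene_id", "sample_id", "fpkm") %in% names(df))) {
    long <- df[c("gene_id", "sample_id", "fpkm")]
  } else {
    if (names(df)[1] != "gene_id") {
      stop("expression matrix must have gene_id as first column", call. = FALSE)
    }
    if (ncol(df) < 2) stop("expression matrix has no sample columns", call. = FALSE)
    if (anyDuplicated(df$gene_id)) {
      stop("duplicated gene_id row(s): ",
           paste(unique(df$gene_id[duplicated(df$gene_id)])[1:3], collapse = ", "),
           call. = FALSE)
    }
    samples <- names(df)[-1]
    long <- data.frame(
      gene_id = rep(df$gene_id, times = length(samples)),
      sample_id = rep(samples, each = nrow(df)),
      fpkm = unlist(df[samples], use.names = FALSE),
      stringsAsFactors = FALSE
    )
  }
  if (!is.numeric(long$fpkm) || anyNA(long$fpkm)) {
    stop("non-numeric FPKM cell(s) in ", path, call. = FALSE)
  }
  if (any(long$fpkm < 0)) stop("negative FPKM value(s) in ", path, call. = FALSE)
  long$log_expr <- log10(long$fpkm + 1)
  long
}

variant_columns <- c("sample_id", "chrom", "pos", "ref", "alt", "gene_id",
                     "effect", "coverage", "in_dbsnp", "in_cosmic",
                     "pred1", "pred2", "pred3", "platform")

variant_effects <- c("missense", "nonsense", "frameshift", "inframe",
                     "splice", "synonymous", "other")

#' Read variant calls
#'
#' MAF-like TSV (columns `sample_id`, `chrom`, `pos`, `ref`, `alt`,
#' `gene_id`, `effect`, `coverage`, `in_dbsnp`, `in_cosmic`, `pred1..pred3`)
#' or VCF v4.x with the same information carried in INFO keys `GENE`,
#' `EFFECT`, `DP`, `DBSNP` (flag), `COSMIC` (flag) and `PRED` (three
#' comma-separated verdicts). Prediction verdicts are `D` (deleterious), `T`
#' (tolerated) or `.` (missing). VCF 1-based positions and TSV positions
#' flagged `pos_base: 1` are shifted to the internal 0-based convention;
#' multi-allelic VCF rows are split into one call per alternate allele so the
#' variant identity key (chrom, pos, ref, alt) is well-defined.
#'
#' @param path Input file path.
#' @param platform `"exome"` or `"transcriptome"`; stamped on every record.
#' @param format `"tsv"` (default) or `"vcf"`.
#' @return A data.frame of variant calls in internal coordinates.
#' @export
read_variants <- function(path, platform = c("exome", "transcriptome"),
                          format = c("tsv", "vcf")) {
  platform <- match.arg(platform)
  format <- match.arg(format)
  if (!file.exists(path)) stop("variant file not found: ", path, call. = FALSE)
  df <- if (format == "tsv") read_variants_tsv(path) else read_variants_vcf(path)
  df$platform <- rep(platform, nrow(df))
  df$chrom <- normalize_chrom(df$chrom)
  validate_variants(df)
  df[variant_columns]
}

read_variants_tsv <- function(path) {
  # explicit classes: a lone "T" allele or verdict must never type-convert
  chr_cols <- c("sample_id", "chrom", "ref", "alt", "gene_id", "effect",
                "pred1", "pred2", "pred3", "platform")
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          na.strings = character(0),
                          colClasses = stats::setNames(
                            rep("character", length(chr_cols)), chr_cols))
  req <- setdiff(variant_columns, "platform")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop("variant file lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (k in c("in_dbsnp", "in_cosmic")) df[[k]] <- as.logical(df[[k]])
  df
}

read_variants_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("reading VCF requires the VariantAnnotation package", call. = FALSE)
  }
  vcf <- VariantAnnotation::expand(VariantAnnotation::readVcf(path))
  if (nrow(vcf) == 0) {
    return(utils::read.delim(text = paste(variant_columns, collapse = "\t")))
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  need <- c("SAMPLE", "GENE", "EFFECT", "DP", "PRED")
  missing_keys <- setdiff(need, names(info))
  if (length(missing_keys) > 0) {
    stop("VCF lacks INFO key(s): ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  }
  p <- info$PRED
  pred <- if (is.list(p) || inherits(p, "List")) lapply(p, as.character)
          else strsplit(as.character(p), ",", fixed = TRUE)
  if (any(lengths(pred) != 3L)) {
    stop("INFO/PRED must hold exactly 3 verdicts per record", call. = FALSE)
  }
  pred <- do.call(rbind, pred)
  data.frame(
    sample_id = as.character(info$SAMPLE),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr) - 1L,  # VCF 1-based -> internal 0-based
    ref = as.character(rr$REF),
    alt = as.character(rr$ALT),
    gene_id = as.character(info$GENE),
    effect = as.character(info$EFFECT),
    coverage = as.integer(info$DP),
    in_dbsnp = if ("DBSNP" %in% names(info)) as.logical(info$DBSNP) else FALSE,
    in_cosmic = if ("COSMIC" %in% names(info)) as.logical(info$COSMIC) else FALSE,
    pred1 = pred[, 1], pred2 = pred[, 2], pred3 = pred[, 3],
    stringsAsFactors = FALSE
  )
}

validate_variants <- function(df) {
  if (any(df$ref == df$alt)) {
    stop("variant with ref == alt at row(s) ",
         paste(utils::head(which(df$ref == df$alt), 5), collapse = ", "),
         call. = FALSE)
  }
  if (any(!grepl("^[ACGTN]+$", df$ref)) || any(!grepl("^[ACGTN*-]+$", df$alt))) {
    stop("malformed allele string(s)", call. = FALSE)
  }
  if (any(df$coverage < 0) || anyNA(df$coverage)) {
    stop("coverage must be a non-negative integer for every variant", call. = FALSE)
  }
  ok <- c("D", "T", ".")
  for (k in c("pred1", "pred2", "pred3")) {
    if (any(!df[[k]] %in% ok)) {
      stop("prediction column ", k, " must be one of D, T, .", call. = FALSE)
    }
  }
  if (any(!df$effect %in% variant_effects)) {
    stop("unknown effect class(es): ",
         paste(unique(setdiff(df$effect, variant_effects)), collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}

#' Set catalog membership flags from a positions-and-alleles catalog
#'
#' dbSNP/COSMIC membership is carried as input columns, never queried live.
#' This helper stamps the flags onto a variant table from a simple catalog
#' table (columns `chrom`, `pos`, `ref`, `alt`, `source` with source in
#' `dbsnp`/`cosmic`), matching on the variant identity key.
#'
#' @param variants A variant data.frame from [read_variants()].
#' @param catalog A catalog data.frame as described above.
#' @return The variant data.frame with `in_dbsnp`/`in_cosmic` replaced.
#' @export
apply_catalog <- function(variants, catalog) {
  stopifnot(all(c("chrom", "pos", "ref", "alt", "source") %in% names(catalog)))
  key <- function(df) paste(normalize_chrom(df$chrom), df$pos, df$ref, df$alt)
  vkey <- key(variants)
  variants$in_dbsnp <- vkey %in% key(catalog[catalog$source == "dbsnp", ])
  variants$in_cosmic <- vkey %in% key(catalog[catalog$source == "cosmic", ])
  variants
}

#' Read fusion candidates
#'
#' TSV with columns `sample_id`, `gene5`, `gene3`, `read_pairs`. A fusion
#' with `gene5 == gene3` is treated as a read-through.
#'
#' @param path Input file path.
#' @return A data.frame of fusion candidates.
#' @export
read_fusions <- function(path) {
  if (!file.exists(path)) stop("fusion file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("sample_id", "gene5", "gene3", "read_pairs")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop("fusion file lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$read_pairs < 0)) stop("read_pairs must be >= 0", call. = FALSE)
  df[req]
}

#' Write a record table as reproducible TSV
#'
#' Writes any of the pipeline's record data.frames as TSV with a one-line
#' `#`-prefixed header naming the package version (and the config hash when a
#' configuration is supplied). Records are sorted by `gene_id`, `sample_id`
#' and the remaining columns, so the same records always produce
#' byte-identical files regardless of input order.
#'
#' @param records A data.frame of records of one type.
#' @param path Output file path.
#' @param config Optional `pipeline_config`; its hash is stamped in the header.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, config = NULL) {
  stopifnot(is.data.frame(records))
  hdr <- paste0("# oncoverge ",
                as.character(utils::packageVersion("oncoverge")))
  if (!is.null(config)) hdr <- paste0(hdr, " config=", config_hash(config))
  if (nrow(records) > 0) {
    keys <- intersect(c("gene_id", "sample_id"), names(records))
    ord_cols <- c(records[keys], records[setdiff(names(records), keys)])
    records <- records[do.call(order, unname(ord_cols)), , drop = FALSE]
  }
  con <- file(path, open = "wb")  # binary mode: identical bytes on any platform
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
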