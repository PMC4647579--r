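# Independent brute-force oracles. These deliberately share no code with the
# implementation: plain loops over every pair, no interval index.

# All-pairs gene x segment CNV calling (dense gene x segment overlap matrix,
# no interval index) with the extremity/amplification/leftmost resolution
# rule.
oracle_gene_cnv <- function(segments, genes, config) {
  rows <- list()
  for (s in unique(segments$sample_id)) {
    seg <- segments[segments$sample_id == s, , drop = FALSE]
    focal <- (seg$end - seg$start) < config$focal_max_length
    amp <- seg$copy_number >= config$amp_min_copies
    del <- seg$copy_number <= config$del_max_copies
    seg <- seg[focal & (amp | del), , drop = FALSE]
    if (nrow(seg) == 0) next
    status <- ifelse(seg$copy_number >= config$amp_min_copies,
                     "amplified", "deleted")
    ext <- abs(seg$copy_number - config$neutral_copies)
    ov <- outer(genes$chrom, seg$chrom, "==") &
      outer(genes$start, seg$end, "<") &
      outer(genes$end, seg$start, ">")
    for (gi in which(rowSums(ov) > 0)) {
      idx <- which(ov[gi, ])
      best <- idx[order(-ext[idx], status[idx] != "amplified",
                        seg$start[idx])][1]
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = genes$gene_id[gi], sample_id = s, status = status[best],
        copy_number = seg$copy_number[best], stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(gene_id = character(0), sample_id = character(0),
                      status = character(0), copy_number = numeric(0)))
  }
  do.call(rbind, rows)
}

# Rank classification of n distinct values by direct enumeration.
oracle_rank_classify <- function(values, high = 60, low = 40) {
  n <- length(values)
  sapply(values, function(v) {
    pct <- 100 * (sum(values < v)) / (n - 1)  # distinct values: rank - 1
    if (pct > high) "high" else if (pct < low) "low" else "intermediate"
  })
}

# Per-gene sample-set union counts from a raw event list.
oracle_cumulative <- function(events, n_samples, gene) {
  ge <- events[events$gene_id == gene, , drop = FALSE]
  length(unique(ge$sample_id)) / n_samples
}

# Distinct alteration types of a gene by re-scanning the raw event list.
oracle_n_types <- function(events, gene) {
  length(unique(events$alteration_type[events$gene_id == gene]))
}

random_gene_segment_instance <- function(seed, n_segments = 200,
                                         n_genes = 2000) {
  set.seed(seed)
  chroms <- as.character(1:3)
  genes <- data.frame(
    gene_id = sprintf("g%d", seq_len(n_genes)),
    symbol = sprintf("g%d", seq_len(n_genes)),
    chrom = sample(chroms, n_genes, replace = TRUE),
    start = sample.int(60e6, n_genes),
    strand = "+", stringsAsFactors = FALSE)
  genes$end <- genes$start + sample.int(200000, n_genes)
  segments <- data.frame(
    sample_id = sample(c("A", "B"), n_segments, replace = TRUE),
    chrom = sample(chroms, n_segments, replace = TRUE),
    start = sample.int(60e6, n_segments),
    copy_number = sample(0:8, n_segments, replace = TRUE),
    stringsAsFactors = FALSE)
  segments$end <- segments$start +
    sample(c(5000, 1e5, 2e6, 9e6, 12e6, 20e6), n_segments, replace = TRUE)
  segments$n_probes <- NA_integer_
  list(genes = genes, segments = segments)
}
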