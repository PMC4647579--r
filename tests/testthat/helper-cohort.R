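# A scaled-down cohort for unit tests (the acceptance suite uses the default
# study conditions).
small_params <- function(seed = 42, ...) {
  simulation_params(n_genes = 400, n_multi_altered = 8, n_single_altered = 20,
                    seed = seed, ...)
}

make_variants <- function(n = 1, sample_id = "S1", chrom = "1",
                          pos = seq_len(n) * 100, ref = "A", alt = "T",
                          gene_id = sprintf("G%d", seq_len(n)),
                          effect = "missense", coverage = 50,
                          in_dbsnp = FALSE, in_cosmic = FALSE,
                          pred1 = "D", pred2 = "D", pred3 = "T",
                          platform = "exome") {
  data.frame(sample_id = sample_id, chrom = chrom, pos = pos, ref = ref,
             alt = alt, gene_id = gene_id, effect = effect,
             coverage = coverage, in_dbsnp = in_dbsnp, in_cosmic = in_cosmic,
             pred1 = pred1, pred2 = pred2, pred3 = pred3,
             platform = platform, stringsAsFactors = FALSE)
}

make_expr <- function(gene_id, sample_id, log_expr) {
  data.frame(gene_id = gene_id, sample_id = sample_id,
             fpkm = 10^log_expr - 1, log_expr = log_expr,
             stringsAsFactors = FALSE)
}
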