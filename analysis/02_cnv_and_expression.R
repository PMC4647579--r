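#!/usr/bin/env Rscript
# Copy-number and expression stages over the simulated cohort.
#
# Segments are split at 10 Mb into focal events (gene-targeted, carried
# forward) and arm-level events (chromosome-scale, excluded); genes are
# annotated onto focal non-neutral segments. Expression is classified per
# sample by percentile rank of log10(FPKM + 1) above the 0.1 noise floor:
# above the 60th percentile is high, below the 40th low.

suppressPackageStartupMessages(library(oncoverge))

cfg <- load_config("results/config.yaml")
cohort <- read_cohort("results/cohort")

seg <- classify_segments(cohort$segments, cfg)
cat(sprintf("segments: %d focal, %d arm-level (excluded from gene calling)\n",
            sum(seg$scale == "focal"), sum(seg$scale == "arm_level")))

cnv_calls <- call_gene_cnv(cohort$segments, cohort$genes, cfg)
write_table(cnv_calls, "results/gene_cnv_calls.tsv", cfg)
cat(sprintf("gene-level CNV calls: %d (%d amplified, %d deleted) across %d genes\n",
            nrow(cnv_calls), sum(cnv_calls$status == "amplified"),
            sum(cnv_calls$status == "deleted"),
            length(unique(cnv_calls$gene_id))))

expr_calls <- classify_expression(cohort$expression, cfg)
write_table(expr_calls, "results/expression_calls.tsv", cfg)
cat("expression status by sample:\n")
print(table(expr_calls$sample_id, expr_calls$status))
cat(sprintf("expressed genes per sample: %s\n",
            paste(tapply(expr_calls$status != "not_expressed",
                         expr_calls$sample_id, sum), collapse = ", ")))
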