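#!/usr/bin/env Rscript
# Cohort-level cumulative alteration frequency over the pooled event table.
#
# For each prioritized gene, the fraction of samples altered by each
# mechanism and by any mechanism (sample-set union, never a sum) is computed,
# genes are filtered at the 3% mutation-frequency floor, and each gene is
# assigned to the three-class typology (mutation-dominant, mixed,
# cnv/expression-dominant) under the default dominance ratio of 3.

suppressPackageStartupMessages(library(oncoverge))

cfg <- load_config("results/config.yaml")
events <- utils::read.delim("results/alteration_events.tsv",
                            comment.char = "#", stringsAsFactors = FALSE)
profiles <- utils::read.delim("results/gene_profiles.tsv",
                              comment.char = "#", stringsAsFactors = FALSE)

samples <- sort(unique(events$sample_id))
prioritized <- sort(profiles$gene_id[profiles$prioritized])
rec <- cumulative_frequency(events, samples, gene_ids = prioritized)
rec <- classify_gene(rec, cfg)
write_table(rec, "results/cohort_frequency.tsv", cfg)

cat(sprintf("cohort of %d samples, %d prioritized genes\n",
            length(samples), nrow(rec)))
cat(sprintf("mean cumulative frequency: %.3f (max per-type mean: %.3f)\n",
            mean(rec$freq_cumulative),
            mean(pmax(rec$freq_mutation, rec$freq_cnv, rec$freq_expression))))
cat("gene classes at dominance ratio 3:\n")
print(table(rec$gene_class))
frequent <- select_frequent_genes(rec, cfg)
cat(sprintf("genes at >= %.0f%% mutation frequency: %d\n",
            100 * cfg$cohort_min_mutation_freq, length(frequent)))
print(utils::head(rec[order(-rec$freq_cumulative),
                      c("gene_id", "freq_mutation", "freq_cnv",
                        "freq_expression", "freq_cumulative", "gene_class")],
                  10))
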