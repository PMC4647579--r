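#!/usr/bin/env Rscript
# Simulate the default 4-sample study cohort and write it to results/cohort/.
#
# The cohort emulates a small head-and-neck cancer cell-line panel profiled
# on three platforms (SNP-array-style copy-number segments, RNA-seq FPKM,
# exome + transcriptome variant calls, fusion candidates), with 20 planted
# multi-altered genes, 100 single-altered decoys and per-filter failing
# records, so every later stage can be checked against known truth.

suppressPackageStartupMessages(library(oncoverge))

cfg <- pipeline_config()
params <- simulation_params()  # fixed default seed: the study conditions
cohort <- simulate_cohort(params, cfg)
paths <- write_cohort(cohort, "results/cohort")
save_config(cfg, "results/config.yaml")

truth <- cohort$truth
cat("cohort written to results/cohort/\n")
cat(sprintf("  genes: %d on %d chromosomes, samples: %d\n",
            nrow(cohort$genes), length(unique(cohort$genes$chrom)),
            params$n_samples))
cat(sprintf("  planted multi-altered: %d, single-altered decoys: %d, clean: %d\n",
            length(truth$multi_altered), length(truth$single_altered),
            length(truth$clean)))
cat(sprintf("  segments: %d, exome variants: %d, transcriptome variants: %d, fusions: %d\n",
            nrow(cohort$segments), nrow(cohort$exome),
            nrow(cohort$transcriptome), nrow(cohort$fusions)))
cat("planted event mix:\n")
print(table(truth$events$alteration_type, truth$events$direction))
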