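#!/usr/bin/env Rscript
# Three-step gene prioritization, judged against the planted truth.
#
# Step 1 selects genes with same-sample concordant focal copy number and
# expression (amplified + high, deleted + low). Step 2 selects mutated genes
# whose transcript is detectable or whose copy number is focally altered.
# Step 3 pools alteration events per candidate gene across all samples and
# prioritizes genes with two or more distinct alteration types.

suppressPackageStartupMessages(library(oncoverge))

cfg <- load_config("results/config.yaml")
cohort <- read_cohort("results/cohort")

res <- run_pipeline(cohort$genes, cohort$segments, cohort$expression,
                    cohort$exome, cohort$transcriptome, cohort$fusions, cfg)
write_table(res$profiles, "results/gene_profiles.tsv", cfg)
write_table(res$events, "results/alteration_events.tsv", cfg)

truth <- sort(cohort$truth$multi_altered)
cat(sprintf("step 1 (CNV~expression concordant): %d genes\n",
            length(res$step1)))
cat(sprintf("step 2 (supported mutations): %d genes\n", length(res$step2)))
cat(sprintf("prioritized (>= %d alteration types): %d genes\n",
            cfg$min_alteration_types, length(res$prioritized)))
cat(sprintf("planted multi-altered: %d; recall %.3f, precision %.3f\n",
            length(truth), mean(truth %in% res$prioritized),
            mean(res$prioritized %in% truth)))

m <- oncoprint_matrix(res$events, sprintf("S%d", 1:4), sort(res$prioritized))
onco <- data.frame(gene_id = rownames(m), as.data.frame(m))
write_table(onco, "results/oncoprint.tsv", cfg)
cat("oncoprint of prioritized genes (A amp, D del, H high, L low, M mutation):\n")
print(m)
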