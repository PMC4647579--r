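#!/usr/bin/env Rscript
# Variant filtering: effect screen, 5X coverage hard filter, dbSNP-not-COSMIC
# germline subtraction, 2-of-3 deleterious vote (truncating variants bypass),
# exome/transcriptome cross-validation, and removal of gene-unassigned calls.
# Every rejected variant is written with the first filter that failed it.

suppressPackageStartupMessages(library(oncoverge))

cfg <- load_config("results/config.yaml")
cohort <- read_cohort("results/cohort")

vs <- run_variant_stage(cohort$exome, cohort$transcriptome, cfg)
write_table(vs$passed, "results/variants_passed.tsv", cfg)
write_table(vs$rejected, "results/variants_rejected.tsv", cfg)

cat(sprintf("exome variants in: %d; passed: %d; rejected: %d\n",
            nrow(cohort$exome), nrow(vs$passed), nrow(vs$rejected)))
cat("rejection reasons (first failing filter):\n")
print(table(vs$rejected$reason))
cat("passed variants by sample and effect:\n")
print(table(vs$passed$sample_id, vs$passed$effect))
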