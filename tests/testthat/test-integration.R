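cfg <- pipeline_config()

cnv_call <- function(gene_id, sample_id, status) {
  data.frame(gene_id = gene_id, sample_id = sample_id, status = status,
             focal = TRUE, copy_number = ifelse(status == "amplified", 4, 1),
             segment_key = "seg", stringsAsFactors = FALSE)
}

test_that("step 1 requires same-sample concordant CNV and expression", {
  expr <- classify_expression(
    make_expr(rep(sprintf("G%d", 1:21), 2),
              rep(c("SA", "SB"), each = 21),
              rep(seq(0.2, 2.2, length.out = 21), 2)), cfg)
  # G21 is the top percentile (high) in both samples; G1 the bottom (low)
  expect_equal(expr$status[expr$gene_id == "G21"], c("high", "high"))
  expect_equal(expr$status[expr$gene_id == "G1"], c("low", "low"))

  concordant_amp <- cnv_call("G21", "SA", "amplified")
  expect_equal(step1_cnv_expression(concordant_amp, expr), "G21")
  concordant_del <- cnv_call("G1", "SA", "deleted")
  expect_equal(step1_cnv_expression(concordant_del, expr), "G1")
  discordant <- cnv_call("G21", "SA", "deleted")   # deleted + high
  expect_equal(step1_cnv_expression(discordant, expr), character(0))
  # amplified in SA but the gene is only middling there? cross-sample high
  # does not rescue: concordance is judged within one sample
  mid_gene <- "G11"
  expect_equal(step1_cnv_expression(cnv_call(mid_gene, "SA", "amplified"),
                                    expr), character(0))
})

test_that("step 2 selects mutated genes via detectable transcript or any CNV call", {
  expr <- classify_expression(
    make_expr(c("GX", "GY", "GZ", "PAD1", "PAD2"), "SA",
              c(0.5, 0.01, 0.01, 0.6, 0.7)), cfg)
  passed <- make_variants(3, gene_id = c("GX", "GY", "GZ"), sample_id = "SA",
                          pos = c(10, 20, 30))
  # GX expressed; GY silent with no CNV; GZ silent but focally deleted in
  # another sample (the "and or altered copy number" route)
  cnv <- cnv_call("GZ", "SB", "deleted")
  got <- step2_mutation_support(passed, expr, cnv)
  expect_setequal(got, c("GX", "GZ"))
  expect_equal(step2_mutation_support(passed[0, ], expr, cnv), character(0))
})

test_that("step 3 pools events across samples and applies the 2-type rule", {
  events <- rbind(
    data.frame(gene_id = "GM", sample_id = "SA", alteration_type = "mutation",
               direction = "not_applicable", evidence = "m"),
    data.frame(gene_id = "GM", sample_id = "SB", alteration_type = "cnv",
               direction = "gain", evidence = "c"),
    data.frame(gene_id = "GM", sample_id = "SB", alteration_type = "expression",
               direction = "gain", evidence = "e"),
    data.frame(gene_id = "GS", sample_id = "SA", alteration_type = "mutation",
               direction = "not_applicable", evidence = "m")
  )
  prof <- step3_prioritize(character(0), c("GM", "GS"), events, cfg)
  expect_equal(prof$gene_id, c("GM", "GS"))  # sorted by n_types desc
  expect_equal(prof$n_types, c(3L, 1L))
  expect_equal(prof$prioritized, c(TRUE, FALSE))
  expect_equal(prof$samples_affected[1], "SA,SB")

  # an expressed mutated gene with no other alteration type is never
  # prioritized: detectability is evidence, not a type
  expect_false(prof$prioritized[prof$gene_id == "GS"])

  # with min_alteration_types = 1, prioritized == step1 union step2
  # (step-1 members always carry at least a cnv + expression event pair)
  events_ga <- rbind(events, data.frame(
    gene_id = "GA", sample_id = "SA", alteration_type = "cnv",
    direction = "gain", evidence = "c"))
  relaxed <- step3_prioritize(c("GA"), c("GM", "GS"), events_ga,
                              pipeline_config(min_alteration_types = 1))
  expect_setequal(relaxed$gene_id[relaxed$prioritized], c("GA", "GM", "GS"))
})

test_that("profile type counts agree with a brute-force re-scan of raw events", {
  set.seed(17)
  genes <- sprintf("G%d", 1:30)
  events <- data.frame(
    gene_id = sample(genes, 200, TRUE),
    sample_id = sample(c("S1", "S2", "S3"), 200, TRUE),
    alteration_type = sample(c("cnv", "expression", "mutation"), 200, TRUE),
    direction = "gain", evidence = "x", stringsAsFactors = FALSE)
  prof <- step3_prioritize(genes, character(0), events, cfg)
  for (i in seq_len(nrow(prof))) {
    expect_equal(prof$n_types[i], oracle_n_types(events, prof$gene_id[i]))
  }
  expect_true(all(prof$n_types[prof$prioritized] >= 2))
  expect_true(all(prof$gene_id %in% genes))
})

test_that("adding a sample never removes a gene from the prioritized set", {
  co <- simulate_cohort(small_params(seed = 5), cfg)
  full <- run_pipeline(co$genes, co$segments, co$expression, co$exome,
                       co$transcriptome, co$fusions, cfg)
  drop_sample <- function(df, s) df[df$sample_id != s, , drop = FALSE]
  s_drop <- "S4"
  reduced <- run_pipeline(co$genes, drop_sample(co$segments, s_drop),
                          drop_sample(co$expression, s_drop),
                          drop_sample(co$exome, s_drop),
                          drop_sample(co$transcriptome, s_drop),
                          drop_sample(co$fusions, s_drop), cfg)
  expect_true(all(reduced$prioritized %in% full$prioritized))
})

test_that("fusions count toward prioritization only when enabled", {
  events_base <- data.frame(
    gene_id = "GF", sample_id = "SA", alteration_type = "mutation",
    direction = "not_applicable", evidence = "m", stringsAsFactors = FALSE)
  fusions <- data.frame(sample_id = "SA", gene5 = "GF", gene3 = "GH",
                        read_pairs = 15, stringsAsFactors = FALSE)
  off <- collect_events(cnv_call("x", "y", "amplified")[0, ],
                        make_expr("z", "SA", 0.5)[0, ] |>
                          transform(percentile = numeric(0),
                                    status = character(0)),
                        make_variants(1, gene_id = "GF", sample_id = "SA"),
                        fusions, cfg)
  expect_false("fusion" %in% off$alteration_type)
  on_cfg <- pipeline_config(count_fusions_in_integration = TRUE)
  on <- collect_events(cnv_call("x", "y", "amplified")[0, ],
                       make_expr("z", "SA", 0.5)[0, ] |>
                         transform(percentile = numeric(0),
                                   status = character(0)),
                       make_variants(1, gene_id = "GF", sample_id = "SA"),
                       fusions, on_cfg)
  expect_equal(sum(on$alteration_type == "fusion"), 2L)
  prof <- step3_prioritize(character(0), "GF", on, on_cfg)
  expect_true(prof$prioritized[prof$gene_id == "GF"])
})
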