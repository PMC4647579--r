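cfg <- pipeline_config()

test_that("simulation is deterministic given the seed", {
  a <- simulate_cohort(small_params(seed = 3), cfg)
  b <- simulate_cohort(small_params(seed = 3), cfg)
  for (part in c("genes", "segments", "expression", "exome", "transcriptome",
                 "fusions")) {
    expect_identical(a[[part]], b[[part]])
  }
  expect_identical(a$truth, b$truth)
  c2 <- simulate_cohort(small_params(seed = 4), cfg)
  expect_false(identical(a$expression$fpkm, c2$expression$fpkm))
})

test_that("truth table partitions the gene universe with the requested counts", {
  p <- small_params(seed = 8)
  co <- simulate_cohort(p, cfg)
  truth <- co$truth
  expect_length(truth$multi_altered, p$n_multi_altered)
  expect_length(truth$single_altered, p$n_single_altered)
  all_genes <- sort(co$genes$gene_id)
  expect_identical(sort(c(truth$multi_altered, truth$single_altered,
                          truth$clean)), all_genes)
  expect_length(intersect(truth$multi_altered, truth$single_altered), 0)
  # every multi-altered gene carries >= 2 distinct planted types; both
  # within-sample and across-sample arrangements occur
  ev <- truth$events
  for (g in truth$multi_altered) {
    expect_gte(oracle_n_types(ev, g), 2L)
  }
  n_samp_per_gene <- tapply(ev$sample_id[ev$gene_id %in% truth$multi_altered],
                            ev$gene_id[ev$gene_id %in% truth$multi_altered],
                            function(s) length(unique(s)))
  expect_true(any(n_samp_per_gene == 1) && any(n_samp_per_gene > 1))
})

test_that("each filter sees at least one passing and one failing record", {
  co <- simulate_cohort(small_params(seed = 8), cfg)
  seg <- classify_segments(co$segments, cfg)
  expect_true(all(c("focal", "arm_level") %in% seg$scale))
  expect_true(any(seg$copy_number == cfg$neutral_copies & seg$scale == "focal"))
  expect_true(any(seg$copy_number >= cfg$amp_min_copies))
  expect_true(any(seg$copy_number <= cfg$del_max_copies))

  vs <- run_variant_stage(co$exome, co$transcriptome, cfg)
  expect_gt(nrow(vs$passed), 0)
  expect_setequal(unique(vs$rejected$reason),
                  c("low_coverage", "dbsnp_only", "not_deleterious",
                    "no_transcriptome_support", "synonymous",
                    "unassigned_gene"))

  expect_true(any(co$fusions$read_pairs >= cfg$min_fusion_read_pairs))
  expect_true(any(co$fusions$read_pairs < cfg$min_fusion_read_pairs))

  ec <- classify_expression(co$expression, cfg)
  expect_true(all(c("not_expressed", "low", "intermediate", "high") %in%
                    ec$status))
})

test_that("noise-level fraction tracks frac_not_expressed within 3 binomial SD", {
  p <- small_params(seed = 12)
  co <- simulate_cohort(p, cfg)
  for (s in unique(co$expression$sample_id)) {
    e <- co$expression[co$expression$sample_id == s, ]
    frac <- mean(e$log_expr < cfg$expr_noise_floor)
    sd3 <- 3 * sqrt(p$frac_not_expressed * (1 - p$frac_not_expressed) /
                      p$n_genes)
    expect_lt(abs(frac - p$frac_not_expressed), sd3)
  }
})

test_that("written cohorts round-trip field-equal and rewrite byte-identically", {
  co <- simulate_cohort(small_params(seed = 19), cfg)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(co, d1)
  write_cohort(co, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6), label = f)
  }
  back <- read_cohort(d1)
  expect_equal(back$segments$copy_number,
               co$segments[order(co$segments$sample_id, co$segments$chrom,
                                 co$segments$start), ]$copy_number)
  expect_setequal(back$genes$gene_id, co$genes$gene_id)
  m1 <- merge(back$expression, co$expression, by = c("gene_id", "sample_id"))
  expect_equal(m1$fpkm.x, m1$fpkm.y, tolerance = 1e-12)
  expect_identical(sort(back$truth$multi_altered), co$truth$multi_altered)
  expect_equal(nrow(back$exome), nrow(co$exome))
  expect_equal(sort(back$fusions$read_pairs), sort(co$fusions$read_pairs))
})

test_that("infeasible parameters error instead of planting colliding genes", {
  p <- simulation_params(n_genes = 5000,
                         genome = stats::setNames(rep(1e6, 2),
                                                  c("1", "2")))
  expect_error(simulate_cohort(p, cfg), "genome too small")
  expect_error(simulation_params(n_multi_altered = 300, n_single_altered = 300,
                                 n_genes = 500), "exceeds n_genes")
})
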