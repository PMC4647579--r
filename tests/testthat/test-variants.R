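cfg <- pipeline_config()

test_that("coverage hard filter: strictly below 5X is removed", {
  v <- make_variants(3, coverage = c(4, 5, 0))
  got <- filter_coverage(v, cfg)
  expect_equal(got$passed$coverage, 5)
  expect_equal(sort(got$rejected$coverage), c(0, 4))
  expect_true(all(got$rejected$reason == "low_coverage"))
})

test_that("germline subtraction: dbSNP-only removed, COSMIC membership rescues", {
  v <- make_variants(4, in_dbsnp = c(TRUE, TRUE, FALSE, FALSE),
                     in_cosmic = c(FALSE, TRUE, FALSE, TRUE))
  got <- subtract_germline(v)
  expect_equal(nrow(got$rejected), 1L)
  expect_true(got$rejected$in_dbsnp & !got$rejected$in_cosmic)
  expect_equal(got$rejected$reason, "dbsnp_only")
  expect_equal(nrow(got$passed), 3L)
})

test_that("2-of-3 vote matches exhaustive enumeration over all 27 verdict triples", {
  verdicts <- c("D", "T", ".")
  grid <- expand.grid(pred1 = verdicts, pred2 = verdicts, pred3 = verdicts,
                      stringsAsFactors = FALSE)
  v <- make_variants(27, pos = 1:27 * 10, pred1 = grid$pred1,
                     pred2 = grid$pred2, pred3 = grid$pred3)
  got <- vote_deleterious(v, cfg)
  want <- rowSums(grid == "D") >= 2        # independent enumeration
  expect_identical(got, unname(want))
  expect_equal(sum(got), 7L)               # exactly 7 of 27 triples pass
})

test_that("truncating effects bypass the vote; missing verdicts never count", {
  v <- make_variants(4, effect = c("nonsense", "frameshift", "splice",
                                   "missense"),
                     pred1 = ".", pred2 = ".", pred3 = c(".", ".", ".", "D"))
  expect_equal(vote_deleterious(v, cfg), c(TRUE, TRUE, TRUE, FALSE))
})

test_that("cross-validation requires an identical sample/position/allele match", {
  ex <- make_variants(3, pos = c(999, 999, 500), alt = c("T", "T", "T"),
                      sample_id = c("S1", "S2", "S1"))
  tr <- make_variants(2, pos = c(999, 500), alt = c("T", "G"),
                      sample_id = "S1", platform = "transcriptome")
  got <- cross_validate(ex, tr, cfg)
  expect_equal(nrow(got$passed), 1L)       # S2 record and allele-mismatch fail
  expect_equal(got$passed$sample_id, "S1")
  expect_equal(got$passed$platform, "exome")  # exome record is retained
  expect_true(all(got$rejected$reason == "no_transcriptome_support"))

  expect_equal(nrow(cross_validate(ex, tr[0, ], cfg)$passed), 0L)

  pos_only <- pipeline_config(cross_validate_alleles = FALSE)
  expect_equal(nrow(cross_validate(ex, tr, pos_only)$passed), 2L)
})

test_that("full stage: first failing reason labels, conservation at every stage", {
  # fails both coverage and germline subtraction: labelled by the first filter
  v <- make_variants(1, coverage = 2, in_dbsnp = TRUE)
  got <- run_variant_stage(v, v[0, ], cfg)
  expect_equal(got$rejected$reason, "low_coverage")

  syn <- make_variants(2, pos = c(10, 20), effect = c("synonymous", "other"),
                       coverage = 1)
  got2 <- run_variant_stage(syn, syn[0, ], cfg)
  expect_true(all(got2$rejected$reason == "synonymous"))

  unassigned <- make_variants(1, gene_id = "")
  got3 <- run_variant_stage(unassigned, unassigned, cfg)
  expect_equal(got3$rejected$reason, "unassigned_gene")

  empty <- run_variant_stage(v[0, ], v[0, ], cfg)
  expect_equal(nrow(empty$passed) + nrow(empty$rejected), 0L)
})

test_that("conservation and idempotence hold on random variant tables", {
  set.seed(21)
  n <- 300
  v <- make_variants(n, pos = seq_len(n) * 3,
                     sample_id = sample(c("S1", "S2"), n, TRUE),
                     effect = sample(c("missense", "synonymous", "nonsense"),
                                     n, TRUE),
                     coverage = sample(0:20, n, TRUE),
                     in_dbsnp = sample(c(TRUE, FALSE), n, TRUE),
                     in_cosmic = sample(c(TRUE, FALSE), n, TRUE),
                     pred1 = sample(c("D", "T", "."), n, TRUE),
                     pred2 = sample(c("D", "T", "."), n, TRUE),
                     pred3 = sample(c("D", "T", "."), n, TRUE))
  tr <- v[sample(n, 150), ]
  got <- run_variant_stage(v, tr, cfg)
  expect_equal(nrow(got$passed) + nrow(got$rejected), n)

  for (f in list(function(x) filter_coverage(x, cfg), subtract_germline)) {
    once <- f(v)$passed
    expect_identical(f(once)$passed, once)     # idempotent
    expect_equal(nrow(f(v)$passed) + nrow(f(v)$rejected), n)
  }
})

test_that("coverage and germline filters commute on the passed set", {
  set.seed(33)
  n <- 200
  v <- make_variants(n, pos = seq_len(n),
                     coverage = sample(0:10, n, TRUE),
                     in_dbsnp = sample(c(TRUE, FALSE), n, TRUE),
                     in_cosmic = sample(c(TRUE, FALSE), n, TRUE))
  a <- subtract_germline(filter_coverage(v, cfg)$passed)$passed
  b <- filter_coverage(subtract_germline(v)$passed, cfg)$passed
  expect_identical(sort(a$pos), sort(b$pos))
  expect_equal(nrow(a), nrow(b))
})
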